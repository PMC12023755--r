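# Shipped simulation scenarios.
#
# The isotope scenarios carry season-level "true" source proportions for the
# four canonical nitrate sources: atmospheric deposition (AP), chemical
# fertilizer (CF), soil nitrogen (SN) and manure & sewage (MS). The default
# signature table is a synthetic stand-in: four well-separated sources in
# (d15N, d18O) space, arranged so each source occupies the region of isotope
# space its real-world counterpart typically occupies (atmospheric nitrate
# high in d18O, manure/sewage high in d15N, fertilizer low in d15N).

#' Default synthetic source signatures
#'
#' Four well-separated synthetic sources in dual-isotope space with
#' per-isotope SDs of 1.5--3 per-mil, zero fractionation and unit
#' concentration weights. These are synthetic stand-ins, not literature
#' end-member values; replace them with measured signatures for real studies.
#'
#' @return A \code{source_signatures} object with sources AP, CF, SN, MS and
#'   isotopes d15n, d18o.
#' @export
default_signatures <- function() {
  # source means form a parallelogram centred at (6, 10) permil:
  # AP = centre + (0, 15), CF = centre + (-10, 0),
  # SN = centre + (0, -15), MS = centre + (10, 0)
  df <- data.frame(
    source  = rep(c("AP", "CF", "SN", "MS"), each = 2L),
    isotope = rep(c("d15n", "d18o"), times = 4L),
    mean_s  = c(6, 25, -4, 10, 6, -5, 16, 10),
    sd_s    = c(2, 3, 1.5, 2, 2, 2, 2.5, 2),
    mean_c  = 0, sd_c = 0, conc_q = 1,
    stringsAsFactors = FALSE
  )
  source_signatures(df)
}

#' Construct a mixture scenario
#'
#' @param name Scenario label.
#' @param true_p Named simplex vector of true source proportions.
#' @param signatures A \code{source_signatures} object.
#' @param residual_sd Per-isotope residual SD (per-mil).
#' @param n_samples Default number of samples to generate.
#' @return A \code{mixture_scenario} object.
#' @export
mixture_scenario <- function(name, true_p, signatures = default_signatures(),
                             residual_sd = c(d15n = 1, d18o = 1),
                             n_samples = 100L) {
  check_simplex(true_p, "true_p")
  if (!setequal(names(true_p), signatures$sources)) {
    stop_domain("true_p names must match the signature table's sources")
  }
  true_p <- true_p[signatures$sources]
  structure(list(name = name, true_p = true_p, signatures = signatures,
                 residual_sd = residual_sd, n_samples = as.integer(n_samples)),
            class = "mixture_scenario")
}

check_simplex <- function(p, what = "p", tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > 1e-6) {
    stop_domain(sprintf("%s must be a simplex vector (non-negative, summing to 1)", what))
  }
  invisible(p)
}

#' Dry-season mixture scenario
#'
#' Atmospheric deposition dominates the dry-season nitrate mixture at 43.9%;
#' the remaining mass is split across fertilizer, soil nitrogen and
#' manure & sewage.
#'
#' @param n_samples Number of samples (default 100).
#' @return A \code{mixture_scenario}.
#' @export
scenario_dry <- function(n_samples = 100L) {
  mixture_scenario("dry",
                   c(AP = 0.439, CF = 0.200, SN = 0.200, MS = 0.161),
                   n_samples = n_samples)
}

#' Wet-season mixture scenario
#'
#' In the wet season chemical fertilizer contributes 23.3% and manure &
#' sewage 26.4% of the nitrate mixture.
#'
#' @param n_samples Number of samples (default 100).
#' @return A \code{mixture_scenario}.
#' @export
scenario_wet <- function(n_samples = 100L) {
  mixture_scenario("wet",
                   c(AP = 0.300, CF = 0.233, SN = 0.203, MS = 0.264),
                   n_samples = n_samples)
}

#' Construct a coupling scenario
#'
#' A single-latent-factor construction: every variable loads on one latent
#' connectivity gradient with loading \eqn{r \in [-1, 1]}, so the pairwise
#' correlation between variable \eqn{i} and the connectivity index converges
#' to \eqn{r_i} and between two variables to \eqn{r_i r_j}. This guarantees a
#' positive-definite joint correlation structure for any loadings.
#'
#' @param name Scenario label.
#' @param loadings Named vector of loadings in [-1, 1]; must include
#'   \code{connectivity}.
#' @param margins Named list of \code{c(mean, sd)} pairs in native units.
#' @param n Default number of records.
#' @return A \code{coupling_scenario} object.
#' @export
coupling_scenario <- function(name, loadings, margins, n = 2000L) {
  if (any(abs(loadings) > 1)) stop_domain("|loading| must be <= 1 for every variable")
  structure(list(name = name, loadings = loadings, margins = margins,
                 n = as.integer(n)), class = "coupling_scenario")
}

#' Connectivity-coupling scenario
#'
#' Dry-season watershed coupling structure: nitrogen concentrations correlate
#' positively with the river-lake connectivity index (TN 0.76, NO3 0.79,
#' NH4 0.75) while alpha-diversity correlates negatively (Chao1 -0.74,
#' Shannon -0.72). Margins are dry-season means/SDs: TN 1.94 +/- 1.22,
#' NO3 1.42 +/- 1.91, NH4 0.23 +/- 0.44 mg/l. Socio-environmental covariates
#' are standardized with moderate positive loadings.
#'
#' @param n Default number of records (default 2000).
#' @return A \code{coupling_scenario}.
#' @export
scenario_coupling <- function(n = 2000L) {
  coupling_scenario(
    "coupling",
    loadings = c(connectivity = 1, tn = 0.76, no3 = 0.79, nh4 = 0.75,
                 chao1 = -0.74, shannon = -0.72,
                 agriculture = 0.30, population = 0.25, wastewater = 0.35,
                 environment = 0.10),
    margins = list(connectivity = c(0.5, 0.2),
                   tn = c(1.94, 1.22), no3 = c(1.42, 1.91), nh4 = c(0.23, 0.44),
                   chao1 = c(3600, 500), shannon = c(5.5, 0.7),
                   agriculture = c(0, 1), population = c(0, 1),
                   wastewater = c(0, 1), environment = c(0, 1)),
    n = n
  )
}

#' Construct a linear-Gaussian structural scenario
#'
#' @param name Scenario label.
#' @param edges Data frame with columns \code{from, to, coef} (standardized
#'   coefficients); the graph must be acyclic.
#' @param n Default number of records.
#' @return A \code{sem_scenario} object; residual SDs are derived so every
#'   variable has unit variance in expectation.
#' @export
sem_scenario <- function(name, edges, n = 5000L) {
  stopifnot(all(c("from", "to", "coef") %in% names(edges)))
  order <- topological_order(edges)  # errors on cycles
  structure(list(name = name, edges = edges, order = order, n = as.integer(n)),
            class = "sem_scenario")
}

#' Connectivity-nitrogen-microbiome path scenario
#'
#' Structural path model in which connectivity drives nitrogen pollution
#' (standardized coefficient 0.43), nitrogen pollution drives the microbial
#' community variable (-0.42; the negative sign reflects the negative
#' diversity correlations, and only the magnitude is compared downstream),
#' and population density drives wastewater discharge (0.51). Agriculture and
#' wastewater feed nitrogen, and environmental factors feed the microbial
#' variable, with free coefficients of 0.30 completing the graph.
#'
#' @param n Default number of records (default 5000).
#' @return A \code{sem_scenario}.
#' @export
scenario_sem <- function(n = 5000L) {
  edges <- data.frame(
    from = c("connectivity", "agriculture", "wastewater", "population",
             "nitrogen", "environment"),
    to   = c("nitrogen", "nitrogen", "nitrogen", "wastewater",
             "microbial", "microbial"),
    coef = c(0.43, 0.30, 0.30, 0.51, -0.42, 0.30),
    stringsAsFactors = FALSE
  )
  sem_scenario("sem", edges, n = n)
}

# Kahn's algorithm; errors if the directed edge set has a cycle.
topological_order <- function(edges) {
  vars <- unique(c(edges$from, edges$to))
  indeg <- vapply(vars, function(v) sum(edges$to == v), integer(1))
  order <- character(0)
  queue <- vars[indeg == 0L]
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    children <- edges$to[edges$from == v]
    for (ch in children) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(vars)) {
    stop(errorCondition("edge set contains a cycle",
                        class = c("nitromix_graph_error", "nitromix_error")))
  }
  order
}
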