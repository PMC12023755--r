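# Synthetic-data generators. All are deterministic given (scenario, seed).

#' Simulate dual-isotope samples from a mixture scenario
#'
#' Draws each observation from the marginal observation model implied by the
#' mixing equation: source and fractionation randomness is folded into a
#' per-isotope normal, so observation \eqn{j} is
#' \eqn{N(m_j, v_j + \sigma_j^2)} with \eqn{m_j} and \eqn{v_j} the
#' concentration-weighted mixture mean and pre-residual variance of
#' \code{\link{mixture_moments}}. This matches the likelihood the fitting
#' routine uses, making simulation and inference self-consistent.
#'
#' @param scenario A \code{mixture_scenario}.
#' @param seed Integer seed.
#' @param n Number of samples (default \code{scenario$n_samples}).
#' @return An \code{isotope_samples} data frame when the scenario's isotopes
#'   are \code{d15n}/\code{d18o}; otherwise a plain data frame with one
#'   column per isotope.
#' @export
generate_isotope_dataset <- function(scenario, seed = 1L, n = scenario$n_samples) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  check_simplex(scenario$true_p, "true_p")
  mom <- mixture_moments(scenario$true_p, scenario$signatures)
  iso <- scenario$signatures$isotopes
  rsd <- scenario$residual_sd
  if (!is.null(names(rsd))) rsd <- rsd[iso]
  total_sd <- sqrt(mom$var + rsd^2)
  set.seed(as.integer(seed))
  vals <- vapply(seq_along(iso),
                 function(j) stats::rnorm(n, mom$mean[j], total_sd[j]),
                 numeric(n))
  colnames(vals) <- iso
  df <- data.frame(sample_id = sprintf("%s_%03d", scenario$name, seq_len(n)),
                   region = "SYN", season = scenario$name,
                   as.data.frame(vals), stringsAsFactors = FALSE)
  if (identical(sort(iso), sort(c("d15n", "d18o")))) as_isotope_samples(df) else df
}

#' Simulate a watershed covariate table with a prescribed coupling structure
#'
#' Single-latent-factor construction: with latent \eqn{Z} standard normal,
#' each variable is \eqn{r_i Z + \sqrt{1 - r_i^2}\, E_i} with independent
#' standard-normal noise, then affinely mapped to its native-unit margin.
#' Pairwise correlations converge to \eqn{r_i r_j} as n grows; the
#' connectivity index has loading 1, so corr(connectivity, variable i)
#' converges to \eqn{r_i}. Nitrogen concentrations are truncated at 0 after
#' mapping (concentrations are non-negative; the truncation bias at the
#' shipped margins is small).
#'
#' @param scenario A \code{coupling_scenario}.
#' @param seed Integer seed.
#' @param n Number of records (default \code{scenario$n}).
#' @return A \code{watershed_table} data frame.
#' @export
generate_watershed_dataset <- function(scenario, seed = 1L, n = scenario$n) {
  stopifnot(inherits(scenario, "coupling_scenario"))
  if (any(abs(scenario$loadings) > 1)) stop_domain("|loading| must be <= 1")
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  out <- data.frame(site_id = sprintf("s%04d", seq_len(n)),
                    season = scenario$name, stringsAsFactors = FALSE)
  out$season <- if (identical(scenario$name, "coupling")) "dry" else scenario$name
  for (v in names(scenario$loadings)) {
    r <- scenario$loadings[[v]]
    e <- stats::rnorm(n)
    std <- r * z + sqrt(1 - r^2) * e
    mg <- scenario$margins[[v]]
    if (is.null(mg)) mg <- c(0, 1)
    x <- mg[1L] + mg[2L] * std
    if (v %in% c("tn", "no3", "nh4")) x <- pmax(x, 0)
    out[[v]] <- x
  }
  # full schema validation only when the scenario covers the watershed CSV
  # columns; partial scenarios (single-variable checks) come back plain
  if (all(watershed_required_cols %in% names(out))) {
    as_watershed_table(out)
  } else {
    out
  }
}

#' Simulate data from a linear-Gaussian structural path model
#'
#' Variables are generated in topological order: exogenous variables are
#' standard normal; each endogenous variable is the coefficient-weighted sum
#' of its parents plus a Gaussian residual whose SD is chosen from the
#' implied covariance so that every variable has unit variance in
#' expectation. Coefficients are therefore standardized path coefficients.
#'
#' @param scenario A \code{sem_scenario}.
#' @param seed Integer seed.
#' @param n Number of records (default \code{scenario$n}).
#' @return A data frame with one standardized column per model variable plus
#'   \code{site_id}.
#' @export
generate_sem_dataset <- function(scenario, seed = 1L, n = scenario$n) {
  stopifnot(inherits(scenario, "sem_scenario"))
  edges <- scenario$edges
  order <- scenario$order
  set.seed(as.integer(seed))
  resid <- sem_residual_sds(edges)
  cols <- list()
  for (v in order) {
    par <- edges[edges$to == v, , drop = FALSE]
    if (nrow(par) == 0L) {
      cols[[v]] <- stats::rnorm(n)
    } else {
      mu <- rep(0, n)
      for (i in seq_len(nrow(par))) mu <- mu + par$coef[i] * cols[[par$from[i]]]
      cols[[v]] <- mu + stats::rnorm(n, sd = resid[[v]])
    }
  }
  df <- data.frame(site_id = sprintf("s%04d", seq_len(n)),
                   cols[order], stringsAsFactors = FALSE)
  df
}

#' Residual SDs that standardize a linear-Gaussian path model
#'
#' Propagates the implied covariance through the graph in topological order
#' and returns, for each endogenous variable, the residual SD that makes its
#' marginal variance exactly 1.
#'
#' @param edges Data frame with columns \code{from, to, coef}.
#' @return Named numeric vector of residual SDs (endogenous variables only).
#' @export
sem_residual_sds <- function(edges) {
  order <- topological_order(edges)
  p <- length(order)
  C <- diag(0, p); dimnames(C) <- list(order, order)
  resid <- numeric(0)
  for (v in order) {
    par <- edges[edges$to == v, , drop = FALSE]
    if (nrow(par) == 0L) {
      C[v, v] <- 1
    } else {
      b <- par$coef; P <- par$from
      pred_var <- as.numeric(t(b) %*% C[P, P, drop = FALSE] %*% b)
      if (pred_var > 1) {
        stop_domain(sprintf(
          "path coefficients into '%s' imply variance %.3f > 1; cannot standardize", v, pred_var))
      }
      resid[v] <- sqrt(1 - pred_var)
      done <- order[seq_len(match(v, order) - 1L)]
      for (u in done) C[v, u] <- C[u, v] <- sum(b * C[P, u])
      C[v, v] <- 1
    }
  }
  resid
}

site_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' Simulate community count tables along a connectivity gradient
#'
#' Each site gets a log-normal relative-abundance profile whose unevenness
#' parameter responds to the (standardized) connectivity index: with a
#' negative \code{diversity_loading}, higher connectivity means a larger
#' log-abundance SD, a less even community, and hence lower Shannon
#' diversity. Counts are multinomial draws at fixed depth. Each site's row
#' depends only on the scenario parameters, the site's connectivity and a
#' per-site stream derived from \code{seed}, so runs are reproducible
#' site-by-site.
#'
#' @param n_sites Number of sites.
#' @param n_taxa Number of taxa (>= 10).
#' @param connectivity Numeric vector of length \code{n_sites}.
#' @param diversity_loading Real in [-1, 1]; sign of the induced
#'   Shannon-connectivity correlation.
#' @param seed Integer seed.
#' @param depth Sequencing depth per site (default 10000).
#' @return A \code{community_table} with per-site metadata (connectivity).
#' @export
generate_community_tables <- function(n_sites, n_taxa, connectivity,
                                      diversity_loading, seed = 1L,
                                      depth = 10000L) {
  if (n_taxa < 10L) stop_domain("n_taxa must be >= 10")
  if (depth <= 0L) stop_domain("depth must be positive")
  if (abs(diversity_loading) > 1) stop_domain("|diversity_loading| must be <= 1")
  stopifnot(length(connectivity) == n_sites)
  z <- if (stats::sd(connectivity) > 0) {
    (connectivity - mean(connectivity)) / stats::sd(connectivity)
  } else rep(0, n_sites)
  counts <- matrix(0L, n_sites, n_taxa,
                   dimnames = list(sprintf("s%03d", seq_len(n_sites)),
                                   sprintf("taxon%04d", seq_len(n_taxa))))
  for (i in seq_len(n_sites)) {
    set.seed(site_seed(seed, i))
    eta <- stats::rnorm(1)  # site-level noise, decoupled from connectivity
    # log-abundance SD: rises with connectivity when diversity_loading < 0
    lsd <- exp(0.4 - 0.8 * diversity_loading * z[i] +
                 0.8 * sqrt(1 - diversity_loading^2) * eta)
    w <- exp(lsd * stats::rnorm(n_taxa))
    counts[i, ] <- as.integer(stats::rmultinom(1L, depth, w / sum(w)))
  }
  community_table(counts,
                  metadata = data.frame(site_id = rownames(counts),
                                        connectivity = connectivity,
                                        stringsAsFactors = FALSE))
}

#' Simulate a pair of distance matrices with a prescribed Mantel correlation
#'
#' The two vectorized upper triangles are bivariate normal with entrywise
#' correlation \code{target_r}, shifted to be positive; the matrices are
#' symmetric with zero diagonals. The expected Mantel correlation between
#' the two matrices equals \code{target_r}.
#'
#' @param n_items Number of items (>= 4).
#' @param target_r Target entrywise correlation in (-1, 1).
#' @param seed Integer seed.
#' @return A list of two \code{dist_matrix} objects, \code{d1} and \code{d2}.
#' @export
generate_correlated_distances <- function(n_items, target_r, seed = 1L) {
  if (n_items < 4L) stop_domain("n_items must be >= 4")
  if (abs(target_r) >= 1) stop_domain("|target_r| must be < 1")
  m <- n_items * (n_items - 1L) / 2L
  set.seed(as.integer(seed))
  u <- stats::rnorm(m)
  v <- target_r * u + sqrt(1 - target_r^2) * stats::rnorm(m)
  # shift to a positive scale; affine maps leave the correlation unchanged
  x <- pmax(6 + u, 0)
  y <- pmax(6 + v, 0)
  labels <- sprintf("i%03d", seq_len(n_items))
  fill <- function(vals) {
    M <- matrix(0, n_items, n_items, dimnames = list(labels, labels))
    M[upper.tri(M)] <- vals
    M <- M + t(M)
    dist_matrix(M, labels)
  }
  list(d1 = fill(x), d2 = fill(y))
}
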