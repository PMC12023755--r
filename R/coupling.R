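# Connectivity-nitrogen-microbiome coupling: correlation suite, piecewise
# structural-equation path model (one least-squares submodel per endogenous
# variable, standardized coefficients), and generic model-evaluation metrics.

#' Correlation with a two-tailed p-value
#'
#' Pearson (t transform) or Spearman (rank transform then t) correlation.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite, non-constant).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return List with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop_domain("x and y must have equal length >= 3")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_domain("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE,
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), method = method)
}

#' Pairwise correlation table
#'
#' Correlates one focal column of a data frame against a set of response
#' columns; raw (uncorrected) p-values are reported.
#'
#' @param data Data frame.
#' @param focal Name of the focal column (e.g. \code{"connectivity"}).
#' @param responses Character vector of response column names.
#' @param method Correlation method, as in \code{\link{correlate}}.
#' @return Data frame with \code{focal, response, r, p, n}.
#' @export
correlation_table <- function(data, focal, responses,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  require_columns(data, c(focal, responses), "correlation table input")
  rows <- lapply(responses, function(v) {
    ct <- correlate(data[[focal]], data[[v]], method)
    data.frame(focal = focal, response = v, r = ct$r, p = ct$p, n = ct$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a piecewise structural-equation path model
#'
#' One ordinary least-squares submodel per endogenous variable, fitted on
#' z-standardized variables, so slopes are standardized path coefficients.
#' Per-endpoint R-squared is the coefficient of determination of each
#' submodel; coefficient p-values come from the usual slope t-test. No
#' global covariance structure or latent variables are fitted.
#'
#' @param data Data frame containing every variable named in \code{edges}.
#' @param edges Data frame with columns \code{from, to} (and optionally
#'   \code{coef}, ignored); the directed graph must be acyclic.
#' @return A \code{path_model}: list with \code{edges} (from, to, coef, se,
#'   p), \code{r_squared} (named, per endogenous variable), \code{n}.
#' @export
fit_path_model <- function(data, edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  vars <- unique(c(edges$from, edges$to))
  require_columns(data, vars, "path model input")
  topological_order(edges)  # errors on cycles
  Z <- as.data.frame(scale(as.data.frame(data)[vars]))
  fitted_edges <- edges[, c("from", "to")]
  fitted_edges$coef <- NA_real_; fitted_edges$se <- NA_real_
  fitted_edges$p <- NA_real_
  r2 <- numeric(0)
  for (v in unique(edges$to)) {
    parents <- edges$from[edges$to == v]
    Xp <- as.matrix(Z[parents])
    if (length(parents) > 1L && kappa(crossprod(Xp)) > 1e8) {
      stop(errorCondition(sprintf("collinear parents for '%s'", v),
                          class = c("nitromix_conditioning_error", "nitromix_error")))
    }
    fml <- stats::as.formula(paste(v, "~", paste(parents, collapse = " + ")))
    fit <- stats::lm(fml, data = Z)
    cf <- summary(fit)$coefficients
    for (pv in parents) {
      i <- which(fitted_edges$from == pv & fitted_edges$to == v)
      fitted_edges$coef[i] <- cf[pv, "Estimate"]
      fitted_edges$se[i] <- cf[pv, "Std. Error"]
      fitted_edges$p[i] <- cf[pv, "Pr(>|t|)"]
    }
    r2[v] <- summary(fit)$r.squared
  }
  structure(list(edges = fitted_edges, r_squared = r2, n = nrow(Z)),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Piecewise path model (n = %d)\n", x$n))
  print(transform(x$edges, coef = round(coef, 3), se = round(se, 3),
                  p = signif(p, 3)))
  cat("R-squared per endpoint:\n")
  print(round(x$r_squared, 3))
  invisible(x)
}

#' Indirect effect along a path
#'
#' Product of the standardized coefficients along an ordered variable chain;
#' every consecutive pair must be a fitted edge.
#'
#' @param model A \code{path_model}.
#' @param path Ordered character vector of variable names (length >= 2).
#' @return The product of the coefficients along the path.
#' @export
indirect_effect <- function(model, path) {
  if (length(path) < 2L) stop_domain("path must name at least two variables")
  eff <- 1
  for (i in seq_len(length(path) - 1L)) {
    hit <- which(model$edges$from == path[i] & model$edges$to == path[i + 1L])
    if (length(hit) != 1L) {
      stop(errorCondition(sprintf("no fitted edge %s -> %s", path[i], path[i + 1L]),
                          class = c("nitromix_path_error", "nitromix_error")))
    }
    eff <- eff * model$edges$coef[hit]
  }
  eff
}

#' Nash-Sutcliffe efficiency
#'
#' \deqn{NSE = 1 - \sum (obs - sim)^2 / \sum (obs - \overline{obs})^2.}
#' 1 for a perfect simulation, 0 for a simulation no better than the
#' observed mean, negative when worse.
#'
#' @param observed,simulated Equal-length numeric vectors (n >= 2; observed
#'   must have positive variance).
#' @return The NSE value.
#' @export
nse <- function(observed, simulated) {
  check_metric_input(observed, simulated)
  1 - sum((observed - simulated)^2) / sum((observed - mean(observed))^2)
}

#' Coefficient of determination as squared Pearson correlation
#'
#' @param observed,simulated Equal-length numeric vectors (n >= 2; both with
#'   positive variance).
#' @return Squared Pearson correlation.
#' @export
r_squared <- function(observed, simulated) {
  check_metric_input(observed, simulated)
  if (stats::sd(simulated) == 0) stop_domain("metric undefined: simulated has zero variance")
  stats::cor(observed, simulated)^2
}

check_metric_input <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 2L) {
    stop_domain("observed and simulated must have equal length >= 2")
  }
  if (stats::sd(observed) == 0) stop_domain("metric undefined: observed has zero variance")
  invisible(NULL)
}
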