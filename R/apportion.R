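# Aggregation of posterior source contributions into non-point (NPS) vs
# point (PS) categories. The default grouping follows the conventional
# classification of nitrate sources: atmospheric deposition, chemical
# fertilizer and soil nitrogen are diffuse (NPS); manure & sewage is the
# point-source category (PS).

#' Define a source-to-category grouping
#'
#' @param groups Named list mapping category names to non-empty character
#'   vectors of source names; categories must be disjoint.
#' @return A \code{source_grouping} object.
#' @export
source_grouping <- function(groups = list(NPS = c("AP", "CF", "SN"), PS = "MS")) {
  all_sources <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_sources)) {
    stop_domain("source grouping: categories must be disjoint")
  }
  if (any(lengths(groups) == 0L)) stop_domain("source grouping: empty category")
  structure(groups, class = "source_grouping")
}

#' Aggregate posterior source proportions into categories
#'
#' Category draws are sums of member-source draws, so the categories inherit
#' the simplex: in every retained draw the category proportions sum to 1.
#'
#' @param posterior A \code{mixing_posterior}.
#' @param grouping A \code{source_grouping} covering the posterior's sources
#'   exactly.
#' @param cred_level Credible level for intervals (default 0.95).
#' @return List with \code{draws} (draws x categories matrix) and
#'   \code{summary} (per-category mean, median, lo, hi).
#' @export
aggregate_sources <- function(posterior, grouping = source_grouping(),
                              cred_level = 0.95) {
  sources <- colnames(posterior$draws_p)
  covered <- unlist(grouping, use.names = FALSE)
  missing <- setdiff(sources, covered)
  if (length(missing) > 0L) {
    stop_domain(sprintf("source(s) not covered by any category: %s",
                        paste(missing, collapse = ", ")))
  }
  extra <- setdiff(covered, sources)
  if (length(extra) > 0L) {
    stop_domain(sprintf("grouping names unknown source(s): %s",
                        paste(extra, collapse = ", ")))
  }
  draws <- vapply(grouping, function(members) {
    rowSums(posterior$draws_p[, members, drop = FALSE])
  }, numeric(nrow(posterior$draws_p)))
  a <- (1 - cred_level) / 2
  summary <- data.frame(category = colnames(draws),
                        mean = colMeans(draws),
                        median = apply(draws, 2L, stats::median),
                        lo = apply(draws, 2L, stats::quantile, probs = a),
                        hi = apply(draws, 2L, stats::quantile, probs = 1 - a),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(draws = draws, summary = summary)
}

#' Long-format contribution table across strata
#'
#' One row per stratum and per source or category, with posterior mean and
#' equal-tailed interval expressed as percentages. Within each stratum the
#' source-row percentages sum to 100 and the category-row percentages sum
#' to 100.
#'
#' @param posteriors Named list of \code{mixing_posterior} objects (names are
#'   stratum labels), or a list of \code{(label, posterior)} pairs.
#' @param grouping A \code{source_grouping}.
#' @param cred_level Credible level (default 0.95).
#' @return Data frame with columns
#'   \code{stratum, name, kind, mean_pct, lo_pct, hi_pct}.
#' @export
contribution_table <- function(posteriors, grouping = source_grouping(),
                               cred_level = 0.95) {
  if (length(posteriors) < 1L) stop_domain("need at least one stratum")
  labels <- names(posteriors)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop_domain("posteriors must be a named list (stratum labels)")
  }
  if (anyDuplicated(labels)) stop_domain("duplicate stratum labels")
  a <- (1 - cred_level) / 2
  rows <- list()
  for (lab in labels) {
    post <- posteriors[[lab]]
    src <- post$draws_p
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = lab, name = colnames(src), kind = "source",
      mean_pct = 100 * colMeans(src),
      lo_pct = 100 * apply(src, 2L, stats::quantile, probs = a),
      hi_pct = 100 * apply(src, 2L, stats::quantile, probs = 1 - a),
      row.names = NULL, stringsAsFactors = FALSE)
    agg <- aggregate_sources(post, grouping, cred_level)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = lab, name = agg$summary$category, kind = "category",
      mean_pct = 100 * agg$summary$mean,
      lo_pct = 100 * agg$summary$lo,
      hi_pct = 100 * agg$summary$hi,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
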