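# Community diversity, dissimilarity, ordination and permutation tests,
# implemented from first principles on sites-by-taxa count matrices.
# vegan's implementations serve as independent cross-checks in the test
# suite, never as the computation path.

check_counts <- function(counts) {
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  if (sum(counts) <= 0) stop_domain("counts must contain at least one positive value")
  counts
}

#' Chao1 richness estimator
#'
#' Bias-corrected form
#' \deqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}
#' with \eqn{F_1}, \eqn{F_2} the singleton and doubleton counts; defined even
#' when no doubletons are present. \code{bias_corrected = FALSE} gives the
#' classical \eqn{S_{obs} + F_1^2 / (2 F_2)} form (infinite when
#' \eqn{F_2 = 0} and \eqn{F_1 > 0}).
#'
#' @param counts Non-negative integer vector of per-taxon counts.
#' @param bias_corrected Use the bias-corrected form (default TRUE).
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else if (f1 > 0) {
    Inf
  } else {
    s_obs
  }
}

#' Shannon diversity (natural-log units)
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over taxa with positive relative
#' abundance; 0 for a single-taxon community.
#'
#' @param counts Non-negative vector of per-taxon counts.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(counts) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Simpson dominance index
#'
#' The dominance form \eqn{D = \sum_i p_i^2} (lower = more even; 1 for a
#' single-taxon community). The complements \eqn{1 - D} (Gini-Simpson) and
#' \eqn{1/D} (inverse Simpson) are available via \code{form}.
#'
#' @param counts Non-negative vector of per-taxon counts.
#' @param form One of \code{"dominance"} (default), \code{"gini"},
#'   \code{"inverse"}.
#' @return Simpson index in the requested form.
#' @export
simpson <- function(counts, form = c("dominance", "gini", "inverse")) {
  form <- match.arg(form)
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  D <- sum(p^2)
  switch(form, dominance = D, gini = 1 - D, inverse = 1 / D)
}

#' Per-site alpha-diversity table
#'
#' Computes Chao1, Shannon (nats) and the Simpson dominance index for every
#' site of a community table, alongside observed richness and depth. A
#' warning is issued when site depths differ by more than tenfold, since
#' none of the indices is depth-normalized here.
#'
#' @param tab A \code{community_table}.
#' @return Data frame with one row per site: \code{site_id, depth, richness,
#'   chao1, shannon, simpson, simpson_gini, simpson_inverse}.
#' @export
alpha_diversity <- function(tab) {
  counts <- tab$counts
  depths <- rowSums(counts)
  if (any(depths <= 0)) stop_domain("every site must have a positive total count")
  if (max(depths) / min(depths) > 10) {
    warning("site depths differ by more than 10x; consider depth normalization")
  }
  data.frame(
    site_id = rownames(counts),
    depth = depths,
    richness = rowSums(counts > 0),
    chao1 = apply(counts, 1L, chao1),
    shannon = apply(counts, 1L, shannon),
    simpson = apply(counts, 1L, simpson),
    simpson_gini = apply(counts, 1L, simpson, form = "gini"),
    simpson_inverse = apply(counts, 1L, simpson, form = "inverse"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(a, b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)}, in [0, 1]:
#' 0 for identical abundance profiles, 1 for fully disjoint ones.
#'
#' @param tab A \code{community_table} (>= 2 sites, all with positive totals).
#' @return A \code{dist_matrix} of pairwise dissimilarities.
#' @export
bray_curtis <- function(tab) {
  counts <- tab$counts
  n <- nrow(counts)
  if (n < 2L) stop_domain("need at least two sites")
  if (any(rowSums(counts) <= 0)) stop_domain("every site must have a positive total count")
  D <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      num <- sum(abs(counts[i, ] - counts[j, ]))
      den <- sum(counts[i, ] + counts[j, ])
      D[i, j] <- D[j, i] <- num / den
    }
  }
  dist_matrix(D)
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers \eqn{-D^2/2} with Gower centering and eigendecomposes it.
#' Coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues; the proportion explained by an axis is its eigenvalue over
#' the sum of positive eigenvalues. Negative eigenvalues (non-Euclidean
#' input) are dropped from both coordinates and proportions.
#'
#' @param d A \code{dist_matrix}.
#' @param n_axes Number of axes to return (default 2; silently truncated to
#'   the number of positive eigenvalues, with a warning).
#' @return List with \code{coordinates} (sites x axes),
#'   \code{proportion_explained} (per returned axis) and
#'   \code{eigenvalues} (all).
#' @export
pcoa <- function(d, n_axes = 2L) {
  D <- unclass(d)
  n <- nrow(D)
  G <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% G %*% C
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  if (n_axes > length(pos)) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes",
                    length(pos), length(pos)))
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  dimnames(coords) <- list(rownames(D), paste0("PCoA", seq_len(n_axes)))
  list(coordinates = coords,
       proportion_explained = e$values[keep] / sum(e$values[pos]),
       eigenvalues = e$values)
}

upper_tri_vec <- function(M) M[upper.tri(M)]

align_dist <- function(d1, d2) {
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (!setequal(l1, l2)) {
    stop(errorCondition("distance matrices have mismatched labels",
                        class = c("nitromix_alignment_error", "nitromix_error")))
  }
  idx <- match(l1, l2)
  list(d1 = unclass(d1), d2 = unclass(d2)[idx, idx, drop = FALSE])
}

#' Mantel test between two distance matrices
#'
#' The statistic is the (Pearson or Spearman) correlation of the vectorized
#' upper triangles. The one-tailed p-value permutes the rows and columns of
#' the second matrix jointly, with the observed statistic included in the
#' null: \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})}.
#'
#' @param d1,d2 \code{dist_matrix} objects with matching labels (>= 4 items).
#' @param n_perm Number of permutations (default 999).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param seed Integer seed for the permutations.
#' @return List with \code{r}, \code{p}, \code{n_perm}.
#' @export
mantel <- function(d1, d2, n_perm = 999L, method = c("pearson", "spearman"),
                   seed = 1L) {
  method <- match.arg(method)
  if (nrow(d1) < 4L) stop_domain("need at least 4 items")
  al <- align_dist(d1, d2)
  x <- upper_tri_vec(al$d1)
  if (method == "spearman") x <- rank(x)
  n <- nrow(al$d1)
  stat <- function(M2) {
    y <- upper_tri_vec(M2)
    if (method == "spearman") y <- rank(y)
    stats::cor(x, y)
  }
  r_obs <- stat(al$d2)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (stat(al$d2[perm, perm]) >= r_obs) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based statistic
#' \deqn{R = (\bar r_B - \bar r_W) / (M / 2), \quad M = n(n-1)/2,}
#' where \eqn{\bar r_B} and \eqn{\bar r_W} are the mean ranks (midranks for
#' ties) of between- and within-group pairwise distances. R is 1 when every
#' between-group distance exceeds every within-group distance and about 0
#' when grouping is unrelated to the distances. The p-value permutes group
#' labels, one-tailed, with the "+1" convention as in \code{\link{mantel}}.
#'
#' @param d A \code{dist_matrix}.
#' @param groups Group labels, one per item (>= 2 groups, each of size >= 2).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with \code{R}, \code{p}, \code{n_perm}.
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = 1L) {
  D <- unclass(d)
  n <- nrow(D)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_domain("need >= 2 groups, each with >= 2 members")
  }
  rks <- matrix(0, n, n)
  rks[upper.tri(rks)] <- rank(upper_tri_vec(D))
  M <- n * (n - 1) / 2
  ut <- which(upper.tri(D), arr.ind = TRUE)
  r_vec <- rks[upper.tri(rks)]
  stat <- function(g) {
    within <- g[ut[, 1L]] == g[ut[, 2L]]
    (mean(r_vec[!within]) - mean(r_vec[within])) / (M / 2)
  }
  R_obs <- stat(groups)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (stat(sample(groups)) >= R_obs) exceed <- exceed + 1L
  }
  list(R = R_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Distance matrix from a single environmental variable
#'
#' Absolute pairwise differences of a scalar covariate, for use as the
#' environmental side of a Mantel test against community dissimilarity.
#'
#' @param x Numeric vector.
#' @param labels Item labels (default names of \code{x} or e1..en).
#' @return A \code{dist_matrix}.
#' @export
env_distance <- function(x, labels = names(x)) {
  if (is.null(labels)) labels <- paste0("e", seq_along(x))
  dist_matrix(abs(outer(x, x, "-")), labels)
}
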