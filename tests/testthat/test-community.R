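test_that("diversity indices match hand-computed values and invariants", {
  # Chao1
  expect_equal(chao1(c(3, 3, 3)), 3)
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)
  expect_equal(chao1(c(1, 1, 1, 1)), 10)  # F2 = 0 branch
  expect_identical(chao1(c(1, 1, 3), bias_corrected = FALSE), Inf)
  expect_error(chao1(c(0, 0)), class = "nitromix_domain_error")

  # Shannon
  expect_equal(shannon(c(2, 2, 2, 2)), log(4))
  expect_equal(shannon(c(7)), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.0397, tolerance = 1e-4)

  # Simpson (dominance)
  expect_equal(simpson(c(5)), 1)
  expect_equal(simpson(rep(3, 8)), 1 / 8)
  expect_equal(simpson(c(1, 1, 2)), 0.375)
  expect_equal(simpson(c(1, 1, 2), form = "gini"), 0.625)
  expect_equal(simpson(c(1, 1, 2), form = "inverse"), 1 / 0.375)

  # permutation invariance to taxon order; chao1 >= richness
  set.seed(1)
  for (rep_ in 1:5) {
    v <- stats::rpois(30, 2)
    v[1] <- v[1] + 1L  # ensure non-empty
    perm <- sample(v)
    expect_equal(shannon(v), shannon(perm))
    expect_equal(simpson(v), simpson(perm))
    expect_equal(chao1(v), chao1(perm))
    expect_gte(chao1(v), sum(v > 0))
  }

  # Shannon maximal / Simpson minimal at uniformity for fixed richness
  expect_gt(shannon(c(5, 5, 5)), shannon(c(12, 2, 1)))
  expect_lt(simpson(c(5, 5, 5)), simpson(c(12, 2, 1)))
})

test_that("diversity indices agree with vegan on a simulated table", {
  skip_if_not_installed("vegan")
  tab <- generate_community_tables(12L, 80L, seq(0, 1, length.out = 12L),
                                   -0.5, seed = 3L)
  div <- alpha_diversity(tab)
  expect_equal(div$shannon, unname(vegan::diversity(tab$counts, "shannon")),
               tolerance = 1e-10)
  expect_equal(1 - div$simpson, unname(vegan::diversity(tab$counts, "simpson")),
               tolerance = 1e-10)
  expect_equal(div$chao1, unname(vegan::estimateR(tab$counts)["S.chao1", ]),
               tolerance = 1e-8)
})

test_that("Bray-Curtis matches hand values, vegan, and its bounds", {
  m <- matrix(c(1, 2, 2, 1), 2L, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  d <- bray_curtis(community_table(m))
  expect_equal(d["a", "b"], 2 / 6)

  ident <- matrix(c(3, 1, 3, 1), 2L, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  expect_equal(bray_curtis(community_table(ident))["a", "b"], 0)
  disj <- matrix(c(3, 0, 0, 5), 2L, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  expect_equal(bray_curtis(community_table(disj))["a", "b"], 1)

  skip_if_not_installed("vegan")
  tab <- generate_community_tables(10L, 60L, seq(0, 1, length.out = 10L),
                                   -0.5, seed = 4L)
  got <- bray_curtis(tab)
  want <- as.matrix(vegan::vegdist(tab$counts, "bray"))
  expect_equal(unclass(got), want, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCoA reproduces geometry: collinear, equilateral, and reconstruction", {
  # three collinear points: axis 1 explains everything
  pts <- cbind(c(0, 1, 3), 0)
  D <- dist_matrix(as.matrix(stats::dist(pts)), c("a", "b", "c"))
  ord <- pcoa(D, 1L)
  expect_equal(ord$proportion_explained[1L], 1, tolerance = 1e-10)

  # equilateral triangle: two axes, 50% each
  tri <- dist_matrix(matrix(1, 3, 3) - diag(3), c("a", "b", "c"))
  ord2 <- pcoa(tri, 2L)
  expect_equal(ord2$proportion_explained, c(0.5, 0.5), tolerance = 1e-10)

  # distances in full-rank PCoA space reproduce a Euclidean input
  set.seed(5)
  X <- matrix(stats::rnorm(6 * 4), 6, 4)
  D6 <- dist_matrix(as.matrix(stats::dist(X)))
  full <- suppressWarnings(pcoa(D6, 6L))
  rec <- as.matrix(stats::dist(full$coordinates))
  expect_lt(max(abs(rec - unclass(D6))), 1e-8)
  # no materially negative eigenvalues for Euclidean input
  expect_gt(min(full$eigenvalues) / max(full$eigenvalues), -1e-8)

  skip_if_not_installed("ape")
  ape_ord <- ape::pcoa(stats::as.dist(unclass(D6)))
  expect_equal(abs(full$coordinates[, 1L]),
               abs(ape_ord$vectors[, 1L]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("Mantel statistic and p-value agree with exhaustive enumeration at n = 4", {
  set.seed(6)
  X1 <- matrix(stats::rnorm(4 * 2), 4, 2)
  X2 <- X1 + matrix(stats::rnorm(4 * 2, 0, 0.7), 4, 2)
  d1 <- dist_matrix(as.matrix(stats::dist(X1)), paste0("i", 1:4))
  d2 <- dist_matrix(as.matrix(stats::dist(X2)), paste0("i", 1:4))
  oracle <- oracle_mantel_exhaustive(unclass(d1), unclass(d2))
  got <- mantel(d1, d2, n_perm = 9999L, seed = 2L)
  expect_equal(got$r, oracle$r, tolerance = 1e-12)
  expect_lt(abs(got$p - oracle$p), 0.02)
})

test_that("Mantel identity, null behaviour, and label alignment", {
  gd <- generate_correlated_distances(20L, 0.5, seed = 7L)
  self <- mantel(gd$d1, gd$d1, n_perm = 199L, seed = 1L)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)

  # independent matrices: p rarely small, r near 0
  small_p <- 0L
  rs <- numeric(10L)
  for (s in 1:10) {
    a <- generate_correlated_distances(30L, 0, seed = 300L + s)
    mt <- mantel(a$d1, a$d2, n_perm = 99L, seed = s)
    rs[s] <- mt$r
    if (mt$p <= 0.05) small_p <- small_p + 1L
  }
  expect_lte(small_p, 1L)
  expect_lt(stats::median(abs(rs)), 0.1)

  d_bad <- dist_matrix(unclass(gd$d2), paste0("x", seq_len(20L)))
  expect_error(mantel(gd$d1, d_bad), class = "nitromix_alignment_error")

  # spearman variant runs and is seed-reproducible
  m1 <- mantel(gd$d1, gd$d2, n_perm = 99L, method = "spearman", seed = 3L)
  m2 <- mantel(gd$d1, gd$d2, n_perm = 99L, method = "spearman", seed = 3L)
  expect_identical(m1, m2)
})

test_that("ANOSIM matches its limits, a rank oracle, and vegan", {
  # two tight clusters far apart: R = 1
  pts <- rbind(matrix(stats::rnorm(8, 0, 0.1), 4), matrix(stats::rnorm(8, 10, 0.1), 4))
  D <- dist_matrix(as.matrix(stats::dist(pts)))
  groups <- rep(c("g1", "g2"), each = 4L)
  a <- anosim(D, groups, n_perm = 99L, seed = 1L)
  expect_equal(a$R, 1)

  # all distances equal: R = 0
  Deq <- dist_matrix(matrix(1, 6, 6) - diag(6))
  aeq <- anosim(Deq, rep(c("a", "b"), each = 3L), n_perm = 99L, seed = 1L)
  expect_equal(aeq$R, 0)

  # 8-site toy example vs direct rank arithmetic
  set.seed(8)
  X <- matrix(stats::rnorm(8 * 3), 8, 3)
  D8 <- dist_matrix(as.matrix(stats::dist(X)))
  g8 <- rep(c("u", "v"), each = 4L)
  expect_equal(anosim(D8, g8, n_perm = 9L, seed = 1L)$R,
               oracle_anosim_R(unclass(D8), g8), tolerance = 1e-12)

  skip_if_not_installed("vegan")
  va <- vegan::anosim(stats::as.dist(unclass(D8)), g8, permutations = 9)
  expect_equal(anosim(D8, g8, n_perm = 9L, seed = 1L)$R,
               unname(va$statistic), tolerance = 1e-12)

  expect_error(anosim(D8, c(rep("u", 7L), "v")),
               class = "nitromix_domain_error")
})

test_that("distances are equivariant to site order", {
  tab <- generate_community_tables(8L, 50L, seq(0, 1, length.out = 8L),
                                   -0.5, seed = 9L)
  d <- bray_curtis(tab)
  perm <- sample(8L)
  tab_p <- community_table(tab$counts[perm, ])
  d_p <- bray_curtis(tab_p)
  expect_equal(unclass(d_p), unclass(d)[perm, perm])
})
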