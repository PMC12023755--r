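test_that("isotope generator is seed-deterministic and honours degenerate limits", {
  sc <- scenario_dry(n_samples = 30L)
  a <- generate_isotope_dataset(sc, seed = 11L)
  b <- generate_isotope_dataset(sc, seed = 11L)
  expect_identical(a, b)
  c <- generate_isotope_dataset(sc, seed = 12L)
  expect_false(identical(a$d15n, c$d15n))

  # single source, zero SDs, zero residual: every sample exactly at mu + lambda
  sig1 <- source_signatures(data.frame(
    source = "only", isotope = c("d15n", "d18o"),
    mean_s = c(4, 20), sd_s = 0, mean_c = c(1, -2), sd_c = 0, conc_q = 1))
  sc1 <- mixture_scenario("one", c(only = 1), sig1,
                          residual_sd = c(d15n = 0, d18o = 0), n_samples = 10L)
  d1 <- generate_isotope_dataset(sc1, seed = 1L)
  expect_equal(d1$d15n, rep(5, 10L))
  expect_equal(d1$d18o, rep(18, 10L))
})

test_that("large-n isotope sample mean matches the analytic mixture mean", {
  sc <- scenario_dry()
  mom <- mixture_moments(sc$true_p, sc$signatures)
  d <- generate_isotope_dataset(sc, seed = 1L, n = 50000L)
  se <- sqrt((mom$var + sc$residual_sd^2) / 50000)
  expect_lt(abs(mean(d$d15n) - mom$mean[["d15n"]]), 3 * se[["d15n"]])
  expect_lt(abs(mean(d$d18o) - mom$mean[["d18o"]]), 3 * se[["d18o"]])
})

test_that("watershed generator reproduces its loadings and degenerate limits", {
  # loading 1: exact affine function of connectivity
  sc <- coupling_scenario("t", c(connectivity = 1, tn = 1),
                          list(connectivity = c(0, 1), tn = c(5, 2)), n = 200L)
  w <- generate_watershed_dataset(sc, seed = 3L)
  expect_gt(stats::cor(w$connectivity, w$tn), 1 - 1e-12)

  # loading 0: uncorrelated at large n
  sc0 <- coupling_scenario("t0", c(connectivity = 1, environment = 0),
                           list(connectivity = c(0, 1), environment = c(0, 1)),
                           n = 10000L)
  w0 <- generate_watershed_dataset(sc0, seed = 4L)
  expect_lt(abs(stats::cor(w0$connectivity, w0$environment)), 0.05)

  # shipped scenario: empirical correlation near each loading at n = 2000
  w2 <- generate_watershed_dataset(scenario_coupling(), seed = 1L, n = 2000L)
  expect_lt(abs(stats::cor(w2$connectivity, w2$tn) - 0.76), 0.05)
  expect_lt(abs(stats::cor(w2$connectivity, w2$shannon) - (-0.72)), 0.05)

  expect_error(coupling_scenario("bad", c(connectivity = 1, tn = 1.2),
                                 list(), n = 10L),
               class = "nitromix_domain_error")
})

test_that("structural simulator standardizes variables and recovers coefficients by OLS", {
  # single edge, coefficient 1, residual 0: child equals parent
  e1 <- data.frame(from = "a", to = "b", coef = 1)
  d1 <- generate_sem_dataset(sem_scenario("e1", e1, n = 50L), seed = 5L)
  expect_equal(d1$a, d1$b, tolerance = 1e-12)

  # empty edge set: independent standard normals
  sc_sem <- scenario_sem(n = 4000L)
  d <- generate_sem_dataset(sc_sem, seed = 1L)
  for (v in c("connectivity", "nitrogen", "microbial", "wastewater")) {
    expect_lt(abs(stats::sd(d[[v]]) - 1), 0.06)
    expect_lt(abs(mean(d[[v]])), 0.06)
  }

  # OLS of nitrogen on its parents recovers the generating coefficients
  fit <- stats::lm(nitrogen ~ connectivity + agriculture + wastewater, data = d)
  expect_lt(abs(stats::coef(fit)[["connectivity"]] - 0.43), 0.05)
  expect_lt(abs(stats::coef(fit)[["agriculture"]] - 0.30), 0.05)
  expect_lt(abs(stats::coef(fit)[["wastewater"]] - 0.30), 0.05)

  # cycles are rejected
  expect_error(sem_scenario("cyc", data.frame(from = c("a", "b"),
                                              to = c("b", "a"), coef = 0.5)),
               class = "nitromix_graph_error")
})

test_that("community generator links Shannon diversity to connectivity with the loading's sign", {
  conn <- seq(0, 1, length.out = 200L)
  neg <- generate_community_tables(200L, 120L, conn, -0.9, seed = 2L)
  div_neg <- alpha_diversity(neg)
  expect_lt(stats::cor(div_neg$shannon, conn), -0.3)

  none <- generate_community_tables(200L, 120L, conn, 0, seed = 2L)
  div_none <- alpha_diversity(none)
  expect_lt(abs(stats::cor(div_none$shannon, conn)), 0.1)

  # same seed and parameters: identical counts
  a <- generate_community_tables(5L, 40L, rep(0.5, 5L), -0.5, seed = 9L)
  b <- generate_community_tables(5L, 40L, rep(0.5, 5L), -0.5, seed = 9L)
  expect_identical(a$counts, b$counts)
  # sites with identical per-site conditions give identical rows across calls
  expect_identical(a$counts[2L, ], b$counts[2L, ])

  expect_error(generate_community_tables(5L, 5L, rep(0, 5L), 0, seed = 1L),
               class = "nitromix_domain_error")
  expect_error(generate_community_tables(5L, 40L, rep(0, 5L), 0, seed = 1L,
                                         depth = 0L),
               class = "nitromix_domain_error")
})

test_that("paired distance generator achieves its target correlation and invariants", {
  gd <- generate_correlated_distances(50L, 0.999, seed = 1L)
  expect_equal(unclass(gd$d1), t(unclass(gd$d1)))
  expect_true(all(diag(unclass(gd$d1)) == 0))
  expect_true(all(unclass(gd$d2) >= 0))
  mt <- mantel(gd$d1, gd$d2, n_perm = 99L, seed = 1L)
  expect_gt(mt$r, 0.95)

  expect_error(generate_correlated_distances(50L, 1, seed = 1L),
               class = "nitromix_domain_error")
  expect_error(generate_correlated_distances(3L, 0.5, seed = 1L),
               class = "nitromix_domain_error")
})
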