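test_that("mixture moments match hand limits and a brute-force loop oracle", {
  # single source: mean = mu + lambda, var = omega^2 + tau^2
  sig1 <- source_signatures(data.frame(
    source = "S", isotope = "iso1", mean_s = 3, sd_s = 2,
    mean_c = 1, sd_c = 0.5, conc_q = 2))
  mom1 <- mixture_moments(c(S = 1), sig1)
  expect_equal(unname(mom1$mean), 4)
  expect_equal(unname(mom1$var), 4.25)

  # two equal-weight sources at 0 and 10 with no spread: midpoint, zero var
  sig2 <- toy_signatures(muA = 0, muB = 10, sdA = 0, sdB = 0)
  mom2 <- mixture_moments(c(A = 0.5, B = 0.5), sig2)
  expect_equal(unname(mom2$mean), 5)
  expect_equal(unname(mom2$var), 0)

  # random K = 4, J = 2 case vs straight-loop oracle
  set.seed(42)
  K <- 4L; J <- 2L
  mu <- matrix(stats::rnorm(J * K, 5, 8), J, K)
  omega <- matrix(stats::runif(J * K, 0.5, 3), J, K)
  lambda <- matrix(stats::rnorm(J * K, 0, 1), J, K)
  tau <- matrix(stats::runif(J * K, 0, 1), J, K)
  q <- matrix(stats::runif(J * K, 0.5, 2), J, K)
  df <- data.frame(
    source = rep(paste0("s", seq_len(K)), each = J),
    isotope = rep(paste0("i", seq_len(J)), times = K),
    mean_s = as.vector(mu), sd_s = as.vector(omega),
    mean_c = as.vector(lambda), sd_c = as.vector(tau), conc_q = as.vector(q))
  sig <- source_signatures(df)
  g <- stats::rgamma(K, 1); p <- g / sum(g); names(p) <- paste0("s", seq_len(K))
  got <- mixture_moments(p, sig)
  want <- oracle_moments(p, mu, omega, lambda, tau, q)
  expect_equal(unname(got$mean), want$mean, tolerance = 1e-12)
  expect_equal(unname(got$var), want$var, tolerance = 1e-12)

  expect_error(mixture_moments(c(s1 = 0.9, s2 = 0.9, s3 = 0, s4 = 0), sig),
               class = "nitromix_domain_error")
})

test_that("log-likelihood equals summed normal log-densities and peaks at the mean", {
  sig <- source_signatures(data.frame(
    source = rep(c("A", "B"), each = 2L),
    isotope = rep(c("i1", "i2"), 2L),
    mean_s = c(0, 5, 10, -5), sd_s = c(1, 2, 1.5, 1),
    mean_c = 0, sd_c = 0, conc_q = 1))
  p <- c(A = 0.3, B = 0.7); sigma <- c(0.8, 1.2)
  set.seed(7)
  samples <- data.frame(i1 = stats::rnorm(5, 7, 2), i2 = stats::rnorm(5, -2, 2))
  got <- mixing_log_likelihood(p, sigma, samples, sig)
  mom <- mixture_moments(p, sig)
  want <- 0
  for (i in 1:5) for (j in 1:2) {
    want <- want + stats::dnorm(samples[i, j], mom$mean[j],
                                sqrt(mom$var[j] + sigma[j]^2), log = TRUE)
  }
  expect_equal(got, want, tolerance = 1e-10)

  # standard normal peak: one observation at the mean, unit total variance
  sigu <- toy_signatures(muA = 4, muB = 4, sdA = 0, sdB = 0)
  llpeak <- mixing_log_likelihood(c(A = 0.5, B = 0.5), 1,
                                  data.frame(iso1 = 4), sigu)
  expect_equal(llpeak, -0.5 * log(2 * pi), tolerance = 1e-12)

  # unimodality in the observation
  offs <- c(0, 0.5, 1, 2, 4)
  lls <- vapply(offs, function(o) {
    mixing_log_likelihood(c(A = 0.5, B = 0.5), 1, data.frame(iso1 = 4 + o), sigu)
  }, numeric(1))
  expect_true(all(diff(lls) < 0))

  # zero total variance off the mean: -Inf, not an error
  ll0 <- mixing_log_likelihood(c(A = 0.5, B = 0.5), 0,
                               data.frame(iso1 = 5), sigu)
  expect_identical(ll0, -Inf)
})

test_that("MCMC posterior agrees with dense grid integration on a K=2, J=1 problem", {
  sig <- toy_signatures(muA = 0, muB = 10, sdA = 1, sdB = 1)
  set.seed(3)
  x <- stats::rnorm(15, 0.35 * 0 + 0.65 * 10, 1.5)
  oracle <- oracle_grid_posterior(x, muA = 0, muB = 10, sdA = 1, sdB = 1)
  post <- fit_mixing_model(data.frame(iso1 = x), sig,
                           mixing_config(seed = 2L))
  s <- posterior_summary(post)
  pA <- s[s$parameter == "p_A", ]
  expect_lt(abs(pA$mean - oracle$mean), 0.02)
  expect_lt(abs(pA$lo - oracle$lo), 0.02)
  expect_lt(abs(pA$hi - oracle$hi), 0.02)
})

test_that("every retained draw lies on the simplex and summaries conserve it", {
  sc <- scenario_wet(n_samples = 40L)
  d <- generate_isotope_dataset(sc, seed = 6L)
  post <- fit_mixing_model(d, sc$signatures, test_config(seed = 6L))
  expect_true(all(abs(rowSums(post$draws_p) - 1) < 1e-9))
  expect_true(all(post$draws_p >= 0))
  expect_true(all(post$draws_sigma >= 0))
  s <- posterior_summary(post)
  expect_equal(sum(s$mean[grepl("^p_", s$parameter)]), 1, tolerance = 1e-6)
})

test_that("degenerate and prior-only fits behave as expected", {
  # K = 1: every draw is exactly 1
  sig1 <- source_signatures(data.frame(
    source = "only", isotope = "iso1", mean_s = 2, sd_s = 1,
    mean_c = 0, sd_c = 0, conc_q = 1))
  post1 <- fit_mixing_model(data.frame(iso1 = c(1.8, 2.2, 2.0)), sig1,
                            test_config(seed = 1L))
  expect_true(all(post1$draws_p == 1))

  # zero observations: posterior mean equals the Dirichlet prior mean
  sig <- toy_signatures()
  post0 <- fit_mixing_model(data.frame(iso1 = numeric(0)), sig,
                            test_config(seed = 4L))
  expect_lt(abs(mean(post0$draws_p[, "A"]) - 0.5), 0.03)

  # symmetric two-source problem with all data at the midpoint
  sigs <- toy_signatures(muA = -5, muB = 5, sdA = 1, sdB = 1)
  posts <- fit_mixing_model(data.frame(iso1 = rep(0, 12L)), sigs,
                            test_config(seed = 5L))
  expect_lt(abs(mean(posts$draws_p[, "A"]) - 0.5), 0.05)
})

test_that("permuting source order permutes posterior summaries identically", {
  df <- data.frame(
    source = rep(c("A", "B"), each = 2L),
    isotope = rep(c("i1", "i2"), 2L),
    mean_s = c(0, 0, 10, 10), sd_s = 1, mean_c = 0, sd_c = 0, conc_q = 1)
  sig_ab <- source_signatures(df)
  sig_ba <- source_signatures(df[c(3, 4, 1, 2), ])
  set.seed(8)
  samples <- data.frame(i1 = stats::rnorm(30, 7, 1.5), i2 = stats::rnorm(30, 7, 1.5))
  post_ab <- fit_mixing_model(samples, sig_ab, test_config(seed = 3L))
  post_ba <- fit_mixing_model(samples, sig_ba, test_config(seed = 3L))
  expect_equal(colnames(post_ba$draws_p), c("B", "A"))
  expect_lt(abs(mean(post_ab$draws_p[, "A"]) - mean(post_ba$draws_p[, "A"])), 0.02)
  expect_lt(abs(mean(post_ab$draws_p[, "B"]) - mean(post_ba$draws_p[, "B"])), 0.02)
})

test_that("credible intervals cover scenario truths across seeded replicates", {
  hits <- 0L; total <- 0L
  for (r in seq_len(10L)) {
    sc <- if (r %% 2L == 0L) scenario_dry() else scenario_wet()
    d <- generate_isotope_dataset(sc, seed = 100L + r)
    post <- fit_mixing_model(d, sc$signatures, test_config(seed = 100L + r))
    s <- posterior_summary(post)
    ps <- s[grepl("^p_", s$parameter), ]
    truth <- sc$true_p[sub("^p_", "", ps$parameter)]
    total <- total + 1L
    if (all(truth >= ps$lo & truth <= ps$hi)) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.9)
})

test_that("posterior summary validates inputs and matches sort-based quantiles", {
  sc <- scenario_dry(n_samples = 30L)
  d <- generate_isotope_dataset(sc, seed = 2L)
  post <- fit_mixing_model(d, sc$signatures, test_config(seed = 2L))
  expect_error(posterior_summary(post, cred_level = 1.2),
               class = "nitromix_domain_error")
  s <- posterior_summary(post, 0.9)
  # independent sorted-array quantile for one source
  x <- sort(post$draws_p[, "AP"])
  lo <- unname(stats::quantile(x, 0.05))
  expect_equal(s$lo[s$parameter == "p_AP"], lo, tolerance = 1e-12)

  # degenerate posterior: zero-width intervals
  fake <- post
  fake$draws_p[] <- rep(c(0.4, 0.2, 0.2, 0.2), each = nrow(fake$draws_p))
  sf <- posterior_summary(fake)
  expect_equal(sf$lo[1:4], sf$hi[1:4])
})

test_that("grouped fitting returns one posterior per stratum", {
  sc_d <- scenario_dry(n_samples = 25L); sc_w <- scenario_wet(n_samples = 25L)
  d <- rbind(generate_isotope_dataset(sc_d, seed = 1L),
             generate_isotope_dataset(sc_w, seed = 2L))
  cfg <- mixing_config(n_chains = 2L, n_iter = 1500L, n_burnin = 700L,
                       thin = 2L, seed = 1L)
  fits <- fit_mixing_by_group(d, sc_d$signatures, cfg,
                              group_cols = "season")
  expect_setequal(names(fits), c("dry", "wet"))
  expect_s3_class(fits$dry, "mixing_posterior")
  expect_error(fit_mixing_by_group(d, sc_d$signatures, cfg, "nope"),
               class = "nitromix_schema_error")
})
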