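# Independent oracle implementations used to cross-check the package.
# These deliberately use straight loops / enumeration, not the package's
# own code paths.

# brute-force mixture moments: plain loops over sources
oracle_moments <- function(p, mu, omega, lambda, tau, q) {
  J <- nrow(mu); K <- ncol(mu)
  m <- v <- numeric(J)
  for (j in seq_len(J)) {
    num <- den <- vr <- 0
    for (k in seq_len(K)) {
      num <- num + p[k] * q[j, k] * (mu[j, k] + lambda[j, k])
      den <- den + p[k] * q[j, k]
      vr <- vr + p[k]^2 * q[j, k]^2 * (omega[j, k]^2 + tau[j, k]^2)
    }
    m[j] <- num / den
    v[j] <- vr / den^2
  }
  list(mean = m, var = v)
}

# dense grid integration of the K = 2, J = 1 posterior:
# X_i ~ N(p1*muA + (1-p1)*muB, p1^2 sdA^2 + (1-p1)^2 sdB^2 + sigma^2),
# p1 ~ Uniform(0,1), sigma ~ half-normal(scale)
oracle_grid_posterior <- function(x, muA, muB, sdA, sdB, sigma_scale = 5,
                                  n_p = 401L, n_s = 301L) {
  p_grid <- seq(1e-4, 1 - 1e-4, length.out = n_p)
  s_grid <- seq(1e-3, 4 * stats::sd(x) + 1, length.out = n_s)
  log_post <- matrix(NA_real_, n_p, n_s)
  for (i in seq_len(n_p)) {
    p1 <- p_grid[i]
    m <- p1 * muA + (1 - p1) * muB
    v0 <- p1^2 * sdA^2 + (1 - p1)^2 * sdB^2
    for (s in seq_len(n_s)) {
      V <- v0 + s_grid[s]^2
      log_post[i, s] <- sum(stats::dnorm(x, m, sqrt(V), log = TRUE)) -
        s_grid[s]^2 / (2 * sigma_scale^2)
    }
  }
  w <- exp(log_post - max(log_post))
  marg_p <- rowSums(w); marg_p <- marg_p / sum(marg_p)
  cdf <- cumsum(marg_p)
  list(mean = sum(p_grid * marg_p),
       lo = p_grid[which(cdf >= 0.025)[1L]],
       hi = p_grid[which(cdf >= 0.975)[1L]])
}

# exhaustive Mantel p-value over all relabelings of a small matrix
oracle_mantel_exhaustive <- function(d1, d2) {
  n <- nrow(d1)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  ut <- upper.tri(d1)
  r_obs <- stats::cor(d1[ut], d2[ut])
  rs <- vapply(perms(seq_len(n)), function(pm) {
    stats::cor(d1[ut], d2[pm, pm][ut])
  }, numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs))
}

# direct rank-arithmetic ANOSIM statistic
oracle_anosim_R <- function(D, groups) {
  n <- nrow(D)
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
  }
  dvals <- mapply(function(i, j) D[i, j], pair_i, pair_j)
  rk <- rank(dvals)
  within <- groups[pair_i] == groups[pair_j]
  M <- n * (n - 1) / 2
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

# small well-formed fixture files, built in code
write_isotope_fixture <- function(path, n = 2L) {
  df <- data.frame(sample_id = paste0("s", seq_len(n)),
                   region = "FH", season = "dry",
                   d15n = seq_len(n) + 0.5, d18o = seq_len(n) * 2 - 0.25)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

toy_signatures <- function(muA = 0, muB = 10, sdA = 1, sdB = 1) {
  source_signatures(data.frame(
    source = c("A", "B"), isotope = "iso1",
    mean_s = c(muA, muB), sd_s = c(sdA, sdB),
    mean_c = 0, sd_c = 0, conc_q = 1))
}

# light-but-adequate MCMC settings for unit tests (defaults are heavier)
test_config <- function(seed = 1L) {
  mixing_config(n_chains = 2L, n_iter = 4000L, n_burnin = 2000L, thin = 4L,
                seed = seed)
}
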