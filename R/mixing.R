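# Hierarchical Bayesian dual-isotope mixing model.
#
# Observation model for sample i and isotope j:
#   X_ij = sum_k p_k q_jk (S_jk + C_jk) / sum_k p_k q_jk + eps_ij
#   S_jk ~ N(mu_jk, omega_jk^2)   source signature
#   C_jk ~ N(lambda_jk, tau_jk^2) fractionation
#   eps_ij ~ N(0, sigma_j^2)      residual
# The source and fractionation randomness is integrated out analytically,
# giving the marginal likelihood X_ij ~ N(m_j(p), v_j(p) + sigma_j^2) with
# m_j and v_j from mixture_moments(). Priors: p ~ Dirichlet(alpha),
# sigma_j ~ half-normal(scale). Sampling: covariance-adaptive random-walk
# Metropolis on the free simplex coordinates of p jointly with log sigma.

#' Mixture mean and pre-residual variance per isotope
#'
#' For a proportion vector on the simplex and a signature table, returns the
#' concentration-weighted mixture mean
#' \deqn{m_j = \sum_k p_k q_{jk} (\mu_{jk} + \lambda_{jk}) / \sum_k p_k q_{jk}}
#' and the pre-residual variance
#' \deqn{v_j = \sum_k p_k^2 q_{jk}^2 (\omega_{jk}^2 + \tau_{jk}^2) /
#'   (\sum_k p_k q_{jk})^2.}
#'
#' @param p Simplex vector over the table's sources (named or in table order).
#' @param signatures A \code{source_signatures} object.
#' @return List with numeric vectors \code{mean} and \code{var}, one entry
#'   per isotope (named).
#' @export
mixture_moments <- function(p, signatures) {
  p <- align_p(p, signatures)
  check_simplex(p, "p")
  q  <- signatures$conc_q
  mu <- signatures$mean_s + signatures$mean_c
  s2 <- signatures$sd_s^2 + signatures$sd_c^2
  denom <- as.vector(q %*% p)
  m <- as.vector((q * mu) %*% p) / denom
  v <- as.vector((q^2 * s2) %*% (p^2)) / denom^2
  names(m) <- names(v) <- signatures$isotopes
  list(mean = m, var = v)
}

align_p <- function(p, signatures) {
  if (!is.null(names(p))) {
    if (!setequal(names(p), signatures$sources)) {
      stop_domain("names of p must match the signature table's sources")
    }
    p <- p[signatures$sources]
  }
  if (length(p) != length(signatures$sources)) {
    stop_domain("p must have one element per source")
  }
  as.numeric(p)
}

# sufficient statistics: n, per-isotope mean and centred sum of squares
isotope_suffstats <- function(samples, signatures) {
  iso <- signatures$isotopes
  missing <- setdiff(iso, names(samples))
  if (length(missing) > 0L) {
    stop_schema(sprintf("samples lack isotope column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(samples)[, iso, drop = FALSE])
  storage.mode(X) <- "double"
  list(n = nrow(X), xbar = colMeans(X),
       ss = colSums(sweep(X, 2L, colMeans(X))^2))
}

loglik_suffstats <- function(p, sigma, stats_, signatures) {
  if (stats_$n == 0L) return(0)  # prior-only fit
  mom <- mixture_moments(p, signatures)
  V <- mom$var + sigma^2
  if (any(V <= 0)) {
    dev <- stats_$ss + stats_$n * (stats_$xbar - mom$mean)^2
    if (any(V <= 0 & dev > 0)) return(-Inf)
    V[V <= 0] <- 1  # zero variance, all data exactly at the mean
  }
  sum(-0.5 * stats_$n * log(2 * pi * V) -
        (stats_$ss + stats_$n * (stats_$xbar - mom$mean)^2) / (2 * V))
}

#' Marginal log-likelihood of isotope samples under the mixing model
#'
#' Sum over samples and isotopes of the normal log-density with mean
#' \eqn{m_j(p)} and variance \eqn{v_j(p) + \sigma_j^2}. Degenerate total
#' variance with an off-mean observation yields \code{-Inf} rather than an
#' error.
#'
#' @param p Simplex vector of source proportions.
#' @param sigma Per-isotope residual SDs (>= 0).
#' @param samples Isotope sample data frame (one column per isotope).
#' @param signatures A \code{source_signatures} object.
#' @return Scalar log-likelihood.
#' @export
mixing_log_likelihood <- function(p, sigma, samples, signatures) {
  if (any(sigma < 0)) stop_domain("sigma must be >= 0")
  loglik_suffstats(align_p(p, signatures), as.numeric(sigma),
                   isotope_suffstats(samples, signatures), signatures)
}

#' MCMC configuration for the mixing model
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics;
#'   default 4).
#' @param n_iter Iterations per chain (default 10000).
#' @param n_burnin Burn-in iterations discarded per chain (default 5000).
#' @param thin Thinning interval (default 5).
#' @param prior_alpha Dirichlet concentration for p; scalar or per-source
#'   (default 1, uniform on the simplex).
#' @param sigma_prior_scale Half-normal prior scale for each residual SD,
#'   per-mil (default 5).
#' @param seed Integer seed.
#' @return A \code{mixing_config} list.
#' @export
mixing_config <- function(n_chains = 4L, n_iter = 10000L, n_burnin = 5000L,
                          thin = 5L, prior_alpha = 1, sigma_prior_scale = 5,
                          seed = 1L) {
  if (n_burnin >= n_iter) stop_domain("n_burnin must be < n_iter")
  if (thin < 1L) stop_domain("thin must be >= 1")
  if (any(prior_alpha <= 0)) stop_domain("prior_alpha must be > 0")
  if (any(sigma_prior_scale <= 0)) stop_domain("sigma_prior_scale must be > 0")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 prior_alpha = prior_alpha,
                 sigma_prior_scale = sigma_prior_scale,
                 seed = as.integer(seed)),
            class = "mixing_config")
}

#' Fit the Bayesian mixing model by MCMC
#'
#' Runs \code{n_chains} adaptive random-walk Metropolis chains on the free
#' simplex coordinates of the source proportions jointly with the log
#' residual SDs. During burn-in the global proposal scale adapts toward a
#' 20--40\% acceptance rate and the proposal covariance is learned from the
#' chain history (adaptive Metropolis), after which both are frozen;
#' covariance learning matters because problems with more sources than
#' isotopes leave a posterior ridge. Post-burn-in, thinned draws from all
#' chains are pooled; split-chain potential scale reduction (Rhat) and
#' effective sample sizes are computed per parameter.
#'
#' @param samples Isotope sample data frame (>= 1 row).
#' @param signatures A \code{source_signatures} object.
#' @param config A \code{mixing_config}.
#' @return A \code{mixing_posterior}: list with \code{draws_p}
#'   (draws x K matrix), \code{draws_sigma} (draws x J), \code{chain}
#'   (chain index per draw), \code{diagnostics} (data frame of Rhat/ESS per
#'   parameter), \code{converged} (logical), \code{sources},
#'   \code{isotopes}, \code{accept_rate}.
#' @export
fit_mixing_model <- function(samples, signatures, config = mixing_config()) {
  stopifnot(inherits(signatures, "source_signatures"))
  stats_ <- isotope_suffstats(samples, signatures)
  # n = 0 is permitted: the fit then samples the prior (useful as a check
  # that the sampler reproduces the Dirichlet prior mean)
  K <- length(signatures$sources)
  J <- length(signatures$isotopes)
  alpha <- rep(config$prior_alpha, length.out = K)
  sscale <- rep(config$sigma_prior_scale, length.out = J)
  d_p <- K - 1L
  d <- d_p + J

  # log posterior density in theta = (p_1..p_{K-1}, log sigma). The walk is
  # run directly in simplex coordinates: under-determined mixing problems
  # (more sources than isotopes) leave a posterior ridge that is *linear* in
  # p-space, so a covariance-adapted Gaussian proposal can follow it exactly.
  # Proposals outside the simplex have zero posterior density. The Lebesgue
  # measure on the free coordinates coincides with the simplex measure, so
  # only the log-sigma Jacobian is needed.
  log_post <- function(theta) {
    p <- 1
    if (K > 1L) {
      head <- theta[seq_len(d_p)]
      pk <- 1 - sum(head)
      if (any(head <= 0) || pk <= 0) return(-Inf)
      p <- c(head, pk)
    }
    eta <- theta[d_p + seq_len(J)]
    sigma <- exp(eta)
    ll <- loglik_suffstats(p, sigma, stats_, signatures)
    lp <- sum((alpha - 1) * log(p)) +                 # Dirichlet prior
      sum(-sigma^2 / (2 * sscale^2) + eta)            # half-normal + log Jacobian
    ll + lp
  }
  theta_to_p <- function(theta) {
    if (K == 1L) return(1)
    head <- theta[seq_len(d_p)]
    c(head, 1 - sum(head))
  }

  kept <- floor((config$n_iter - config$n_burnin) / config$thin)
  n_draws <- kept * config$n_chains
  draws_p <- matrix(NA_real_, n_draws, K,
                    dimnames = list(NULL, signatures$sources))
  draws_sigma <- matrix(NA_real_, n_draws, J,
                        dimnames = list(NULL, signatures$isotopes))
  chain_id <- integer(n_draws)
  acc_total <- 0; acc_n <- 0

  for (ch in seq_len(config$n_chains)) {
    set.seed(site_seed(config$seed, ch))
    theta <- init_theta(K, J, alpha, sscale, log_post)
    lp_cur <- log_post(theta)
    # adaptive Metropolis: global scale adapts toward 30% acceptance and the
    # proposal covariance is learned from the burn-in history, so ridge-shaped
    # posteriors (under-determined mixing polygons) still mix well
    log_scale <- log(2.38 / sqrt(d))
    run_mean <- theta; M2 <- diag(0.1, d); n_hist <- 1
    L <- diag(0.05, d)
    e1 <- c(1, rep(0, d - 1L)); w1 <- 0.2
    evec <- diag(d); ewid <- rep(0.2, d)
    row0 <- (ch - 1L) * kept
    k_out <- 0L
    for (it in seq_len(config$n_iter)) {
      # 10% of proposals take a 3x longer step: on ridge-shaped posteriors
      # the occasional long move along the learned covariance decorrelates
      # the weakly identified direction much faster than small steps alone
      step <- if (stats::runif(1) < 0.1) 3 else 1
      prop <- theta + step * exp(log_scale) * as.vector(L %*% stats::rnorm(d))
      lp_prop <- log_post(prop)
      a <- min(1, exp(lp_prop - lp_cur))
      if (stats::runif(1) < a) { theta <- prop; lp_cur <- lp_prop }
      if (it %% 5L == 0L) {
        # slice-sample along the widest learned axis: the weakly identified
        # ridge direction mixes via full-width moves, not diffusion
        sl <- slice_along(theta, lp_cur, e1, w1, log_post)
        theta <- sl$theta; lp_cur <- sl$lp
      }
      if (it %% 7L == 0L) {
        j <- sample.int(d, 1L)
        sl <- slice_along(theta, lp_cur, evec[, j], ewid[j], log_post)
        theta <- sl$theta; lp_cur <- sl$lp
      }
      if (it <= config$n_burnin) {
        log_scale <- log_scale + it^-0.6 * (a - 0.3)
        n_hist <- n_hist + 1
        delta <- theta - run_mean
        run_mean <- run_mean + delta / n_hist
        M2 <- M2 + tcrossprod(delta, theta - run_mean)
        if (it >= 150L && it %% 50L == 0L) {
          cov_hat <- (M2 + t(M2)) / (2 * (n_hist - 1))
          L <- tryCatch(t(chol(cov_hat + diag(1e-8, d))),
                        error = function(e) L)
          ev <- eigen(cov_hat, symmetric = TRUE)
          evec <- ev$vectors
          ewid <- 2 * sqrt(pmax(ev$values, 1e-12))
          e1 <- evec[, 1L]; w1 <- ewid[1L]
        }
        # adaptation freezes after burn-in
      } else {
        acc_total <- acc_total + a; acc_n <- acc_n + 1
        if ((it - config$n_burnin) %% config$thin == 0L && k_out < kept) {
          k_out <- k_out + 1L
          i <- row0 + k_out
          draws_p[i, ] <- theta_to_p(theta)
          draws_sigma[i, ] <- exp(theta[d_p + seq_len(J)])
          chain_id[i] <- ch
        }
      }
    }
  }

  par_mat <- cbind(draws_p, draws_sigma)
  colnames(par_mat) <- c(paste0("p_", signatures$sources),
                         paste0("sigma_", signatures$isotopes))
  diag_df <- mcmc_diagnostics(par_mat, chain_id)
  monitored <- if (K > 1L) diag_df else diag_df[grepl("^sigma_", diag_df$parameter), ]
  converged <- all(is.na(monitored$rhat) | monitored$rhat < 1.05)
  structure(list(draws_p = draws_p, draws_sigma = draws_sigma,
                 chain = chain_id, diagnostics = diag_df,
                 converged = converged,
                 sources = signatures$sources, isotopes = signatures$isotopes,
                 accept_rate = if (acc_n > 0) acc_total / acc_n else NA_real_,
                 config = config),
            class = "mixing_posterior")
}

# univariate slice sampler (stepping out + shrinkage, Neal 2003) along
# direction v from theta; log_post returns -Inf outside the support
slice_along <- function(theta, lp_cur, v, w, log_post, max_steps = 50L) {
  y <- lp_cur + log(stats::runif(1))
  u <- stats::runif(1)
  lo <- -w * u; hi <- lo + w
  k <- 0L
  while (k < max_steps && log_post(theta + lo * v) > y) { lo <- lo - w; k <- k + 1L }
  k <- 0L
  while (k < max_steps && log_post(theta + hi * v) > y) { hi <- hi + w; k <- k + 1L }
  repeat {
    s <- stats::runif(1, lo, hi)
    cand <- theta + s * v
    lp_new <- log_post(cand)
    if (lp_new > y) return(list(theta = cand, lp = lp_new))
    if (s < 0) lo <- s else hi <- s
    if (hi - lo < 1e-12) return(list(theta = theta, lp = lp_cur))
  }
}

init_theta <- function(K, J, alpha, sscale, log_post, max_retries = 100L) {
  for (try in seq_len(max_retries)) {
    g <- stats::rgamma(K, shape = alpha, rate = 1)
    p0 <- g / sum(g)
    p0 <- (p0 + 1e-6) / sum(p0 + 1e-6)
    s0 <- abs(stats::rnorm(J, 0, sscale / 2)) + 0.1
    theta <- c(if (K > 1L) p0[seq_len(K - 1L)], log(s0))
    if (is.finite(log_post(theta))) return(theta)
  }
  stop(errorCondition("could not find a finite-posterior initial state after 100 retries",
                      class = c("nitromix_init_error", "nitromix_error")))
}

# split-chain Rhat and a multi-chain effective sample size (autocovariance
# with Geyer initial-positive truncation), computed per column of par_mat
mcmc_diagnostics <- function(par_mat, chain_id) {
  chains <- sort(unique(chain_id))
  out <- data.frame(parameter = colnames(par_mat),
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  # split each chain in half
  split_list <- list()
  for (ch in chains) {
    idx <- which(chain_id == ch)
    h <- floor(length(idx) / 2)
    if (h >= 2L) {
      split_list <- c(split_list, list(idx[seq_len(h)]), list(idx[h + seq_len(h)]))
    }
  }
  if (length(split_list) < 2L) return(out)
  n <- min(lengths(split_list))
  for (j in seq_len(ncol(par_mat))) {
    x <- vapply(split_list, function(idx) par_mat[idx[seq_len(n)], j], numeric(n))
    m <- ncol(x)
    means <- colMeans(x); vars <- apply(x, 2L, stats::var)
    W <- mean(vars); B <- n * stats::var(means)
    if (W < 1e-300) { out$rhat[j] <- 1; out$ess[j] <- n * m; next }
    var_plus <- (n - 1) / n * W + B / n
    out$rhat[j] <- sqrt(var_plus / W)
    # combined autocovariance (BDA3 eq. 11.7)
    max_lag <- min(n - 2L, 200L)
    rho <- numeric(max_lag)
    acovs <- vapply(seq_len(m), function(cc) {
      a <- stats::acf(x[, cc], lag.max = max_lag, type = "covariance",
                      plot = FALSE, demean = TRUE)$acf[, 1, 1]
      a
    }, numeric(max_lag + 1L))
    for (t in seq_len(max_lag)) {
      rho[t] <- 1 - (W - mean(acovs[t + 1L, ])) / var_plus
    }
    # Geyer: sum while consecutive pairs stay positive
    tau <- 1; t <- 1
    while (t + 1 <= max_lag && (rho[t] + rho[t + 1]) > 0) {
      tau <- tau + 2 * (rho[t] + rho[t + 1]); t <- t + 2
    }
    out$ess[j] <- m * n / max(tau, 1e-12)
  }
  out
}

#' Summarize a mixing posterior
#'
#' Per-source posterior mean, median and equal-tailed credible interval.
#'
#' @param posterior A \code{mixing_posterior} with >= 100 retained draws.
#' @param cred_level Credible level in (0, 1) (default 0.95).
#' @return Data frame with one row per source (then per residual SD):
#'   \code{parameter, mean, median, lo, hi}.
#' @export
posterior_summary <- function(posterior, cred_level = 0.95) {
  if (cred_level <= 0 || cred_level >= 1) stop_domain("cred_level must be in (0, 1)")
  if (nrow(posterior$draws_p) < 100L) stop_domain("need >= 100 retained draws")
  a <- (1 - cred_level) / 2
  summ <- function(mat, prefix) {
    data.frame(parameter = paste0(prefix, colnames(mat)),
               mean = colMeans(mat),
               median = apply(mat, 2L, stats::median),
               lo = apply(mat, 2L, stats::quantile, probs = a),
               hi = apply(mat, 2L, stats::quantile, probs = 1 - a),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(summ(posterior$draws_p, "p_"), summ(posterior$draws_sigma, "sigma_"))
}

#' @export
print.mixing_posterior <- function(x, ...) {
  cat(sprintf("Mixing posterior: %d draws, %d sources (%s), %d isotopes\n",
              nrow(x$draws_p), length(x$sources),
              paste(x$sources, collapse = ", "), length(x$isotopes)))
  cat(sprintf("  converged: %s; mean acceptance: %.2f\n",
              x$converged, x$accept_rate))
  print(utils::head(posterior_summary(x), length(x$sources)))
  invisible(x)
}

#' Fit the mixing model separately per stratum
#'
#' Mirrors stratified reporting: one posterior per unique combination of the
#' grouping columns (for example region and season).
#'
#' @param samples Isotope sample data frame.
#' @param signatures A \code{source_signatures} object.
#' @param config A \code{mixing_config}.
#' @param group_cols Character vector of grouping columns present in
#'   \code{samples} (default \code{c("region", "season")}).
#' @return Named list of \code{mixing_posterior} objects, one per stratum;
#'   names are the grouping values joined by ":".
#' @export
fit_mixing_by_group <- function(samples, signatures, config = mixing_config(),
                                group_cols = c("region", "season")) {
  df <- as.data.frame(samples)
  missing <- setdiff(group_cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("grouping column(s) not found: %s",
                        paste(missing, collapse = ", ")))
  }
  key <- interaction(df[group_cols], sep = ":", drop = TRUE)
  out <- list()
  for (lev in levels(key)) {
    out[[lev]] <- fit_mixing_model(df[key == lev, , drop = FALSE],
                                   signatures, config)
  }
  out
}
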