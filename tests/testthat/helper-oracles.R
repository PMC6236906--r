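# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the HMM oracle enumerates every state path,
# the t-density oracle integrates the normal-gamma mixture by quadrature,
# and the squared-logOR oracle uses the Poisson-mixture series over
# central chi-square densities.

# Exhaustive-path HMM: log-likelihood, smoothed marginals gamma and
# pairwise posteriors eta (list over k = 2..N) from all J^N paths.
brute_force_hmm <- function(log_emis, init, trans) {
  n <- nrow(log_emis); J <- ncol(log_emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(J)), n)))
  logw <- apply(paths, 1, function(z) {
    lw <- log(init[z[1]]) + log_emis[1, z[1]]
    if (n > 1) for (k in 2:n) {
      lw <- lw + log(trans[z[k - 1], z[k]]) + log_emis[k, z[k]]
    }
    lw
  })
  M <- max(logw)
  w <- exp(logw - M)
  loglik <- M + log(sum(w))
  w <- w / sum(w)
  gamma <- matrix(0, n, J)
  for (k in seq_len(n)) for (j in seq_len(J)) {
    gamma[k, j] <- sum(w[paths[, k] == j])
  }
  eta <- list()
  if (n > 1) for (k in 2:n) {
    e <- matrix(0, J, J)
    for (i in seq_len(J)) for (j in seq_len(J)) {
      e[i, j] <- sum(w[paths[, k - 1] == i & paths[, k] == j])
    }
    eta[[k]] <- e
  }
  list(loglik = loglik, gamma = gamma, eta = eta)
}

# Quadrature over the latent gamma scale: t_v(w | mu, k2) as the integral
# of N(w | mu, k2/u) G(u; v/2, v/2) du.
t_mixture_oracle <- function(w, mu, scale2, df) {
  f <- function(u) {
    stats::dnorm(w, mu, sqrt(scale2 / u)) *
      stats::dgamma(u, shape = df / 2, rate = df / 2)
  }
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
}

# Series oracle for the squared-logOR density: X^2/tau^2 ~ chi-square(1)
# with noncentrality delta, written as a Poisson(delta/2) mixture of
# central chi-squares with 1 + 2i df; built from central dchisq only.
logor_sq_series_oracle <- function(x2, zeta, tau2, terms = 200) {
  delta <- zeta^2 / tau2
  i <- 0:terms
  log(sum(exp(stats::dpois(i, delta / 2, log = TRUE) +
                stats::dchisq(x2 / tau2, df = 1 + 2 * i, log = TRUE)))) -
    log(tau2)
}

# Random finite log-emission matrix and valid chain for property tests.
random_hmm_instance <- function(n, J) {
  log_emis <- matrix(stats::rnorm(n * J, sd = 2), n, J)
  init <- stats::runif(J) + 0.1
  init <- init / sum(init)
  trans <- matrix(stats::runif(J * J) + 0.1, J, J)
  trans <- trans / rowSums(trans)
  list(log_emis = log_emis, chain = chain_params(init, trans))
}

# Small heterozygous/homozygous locus table with arbitrary values.
random_loci <- function(n, frac_het = 0.3) {
  het <- stats::runif(n) < frac_het
  data.frame(
    chrom = "1", pos = seq_len(n),
    logR = stats::rnorm(n, 0.3, 0.8),
    logOR = ifelse(het, stats::rnorm(n, 0.5, 0.7), NA_real_),
    het = het, stringsAsFactors = FALSE
  )
}
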