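# Scaled forward-backward recursions, smoothed posteriors and decoding.
#
# Per-step normalization keeps the recursions in (0,1] at N ~ 4e5 loci;
# log emissions are exponentiated after subtracting the per-locus row
# maximum, which re-enters the log-likelihood exactly.

#' Markov chain parameters
#'
#' @param init Length-J initial probability vector \eqn{r_0} (sums to 1).
#' @param trans J x J row-stochastic transition matrix \eqn{P}.
#' @return A `chain_params` list.
#' @export
chain_params <- function(init, trans) {
  trans <- as.matrix(trans)
  J <- length(init)
  stopifnot(nrow(trans) == J, ncol(trans) == J,
            all(init >= 0), all(trans >= 0))
  if (abs(sum(init) - 1) > 1e-8)
    stop("initial probabilities must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  structure(list(init = as.numeric(init), trans = trans),
            class = "chain_params")
}

#' Uniform-start sticky chain
#'
#' Convenience constructor: uniform initial distribution and a transition
#' matrix with a common self-transition probability (off-diagonal mass
#' spread uniformly). With one state the transition matrix is the 1x1
#' identity.
#'
#' @param J Number of states.
#' @param self Self-transition probability (default 0.99).
#' @export
sticky_chain <- function(J, self = 0.99) {
  trans <- if (J == 1L) matrix(1, 1, 1) else {
    m <- matrix((1 - self) / (J - 1), J, J)
    diag(m) <- self
    m
  }
  chain_params(rep(1 / J, J), trans)
}

# Shared setup: shift each row of the log emission matrix by its max and
# exponentiate; the shifts are returned to reconstitute the log-likelihood.
emission_shifted <- function(log_emis) {
  rmax <- apply(log_emis, 1, max)
  list(E = exp(log_emis - rmax), rmax = rmax)
}

#' Scaled forward recursion
#'
#' Runs the forward recursion
#' \eqn{a_j(k) = \sum_i a_i(k-1) P_{ij}\, p(o_k | j)} with per-step
#' normalization, and returns the observed-data log-likelihood
#' \eqn{\log \sum_l a_l(N)} as the sum of log scale factors (plus the
#' row-max shifts applied to the emissions).
#'
#' @param log_emis N x J matrix of finite log emission densities.
#' @param chain A [chain_params] object.
#' @return List with `alpha` (N x J scaled forward variables, rows sum to
#'   1), `scale` (length-N scale factors on the shifted-emission scale),
#'   `rmax` (the per-row shifts) and `loglik`.
#' @export
forward_scaled <- function(log_emis, chain) {
  log_emis <- as.matrix(log_emis)
  n <- nrow(log_emis); J <- ncol(log_emis)
  stopifnot(length(chain$init) == J)
  es <- emission_shifted(log_emis)
  E <- es$E
  alpha <- matrix(0, n, J)
  scale <- numeric(n)
  a <- chain$init * E[1L, ]
  s <- sum(a)
  if (!is.finite(s) || s <= 0)
    stop("forward recursion: zero forward mass at locus 1")
  alpha[1L, ] <- a / s
  scale[1L] <- s
  P <- chain$trans
  for (k in seq_len(n)[-1L]) {
    a <- as.numeric(alpha[k - 1L, ] %*% P) * E[k, ]
    s <- sum(a)
    if (!is.finite(s) || s <= 0)
      stop("forward recursion: zero forward mass at locus ", k)
    alpha[k, ] <- a / s
    scale[k] <- s
  }
  list(alpha = alpha, scale = scale, rmax = es$rmax,
       loglik = sum(log(scale)) + sum(es$rmax))
}

#' Scaled backward recursion
#'
#' Backward recursion \eqn{b_j(k) = \sum_i b_i(k+1) P_{ji}\,
#' p(o_{k+1} | i)} scaled by the forward pass's factors, so that
#' elementwise `alpha * beta` gives normalized smoothed posteriors. The
#' last row is all ones by convention.
#'
#' @inheritParams forward_scaled
#' @param scale Scale factors from the matching [forward_scaled] call.
#' @return N x J matrix of scaled backward variables.
#' @export
backward_scaled <- function(log_emis, chain, scale) {
  log_emis <- as.matrix(log_emis)
  n <- nrow(log_emis); J <- ncol(log_emis)
  E <- emission_shifted(log_emis)$E
  beta <- matrix(0, n, J)
  beta[n, ] <- 1
  P <- chain$trans
  if (n > 1L) {
    for (k in (n - 1L):1L) {
      beta[k, ] <- as.numeric(P %*% (beta[k + 1L, ] * E[k + 1L, ])) / scale[k + 1L]
    }
  }
  beta
}

#' Smoothed state and pairwise posteriors
#'
#' One full forward-backward sweep: per-locus smoothed state posteriors
#' \eqn{\gamma_{kj} = P(Z_k = j \mid \mathrm{data})}, the summed pairwise
#' posteriors \eqn{\sum_{k \ge 2} \eta_k^{i,j}} (the sufficient statistic
#' for the transition M-step) and the observed-data log-likelihood.
#'
#' @inheritParams forward_scaled
#' @return An `hmm_posterior` list with `gamma` (N x J, rows sum to 1),
#'   `pair_sums` (J x J, entries sum to N-1), `loglik`, and `gamma1`
#'   (first-row posterior, for the initial-probability M-step).
#' @export
hmm_posteriors <- function(log_emis, chain) {
  log_emis <- as.matrix(log_emis)
  n <- nrow(log_emis); J <- ncol(log_emis)
  fw <- forward_scaled(log_emis, chain)
  beta <- backward_scaled(log_emis, chain, fw$scale)
  gamma <- fw$alpha * beta
  gamma <- gamma / rowSums(gamma)   # guard tiny numeric drift
  E <- exp(log_emis - fw$rmax)
  pair_sums <- matrix(0, J, J)
  P <- chain$trans
  if (n > 1L) {
    for (k in seq_len(n)[-1L]) {
      eta <- (fw$alpha[k - 1L, ] %o% (E[k, ] * beta[k, ])) * P / fw$scale[k]
      pair_sums <- pair_sums + eta
    }
  }
  structure(list(gamma = gamma, pair_sums = pair_sums,
                 loglik = fw$loglik, gamma1 = gamma[1L, ]),
            class = "hmm_posterior")
}

#' Posterior-mode decoding
#'
#' Assigns each locus the state with the largest smoothed posterior
#' (MAP-per-locus, the primary decoder); ties break toward the lowest
#' state index.
#'
#' @param gamma N x J matrix of smoothed posteriors.
#' @return Integer vector of 1-based state indices.
#' @export
decode_map <- function(gamma) {
  max.col(as.matrix(gamma), ties.method = "first")
}

#' Viterbi decoding (secondary)
#'
#' Most probable joint state path, provided for comparison with
#' [decode_map]; per-locus posterior-mode decoding is the primary decoder.
#'
#' @inheritParams forward_scaled
#' @return Integer vector of 1-based state indices.
#' @export
decode_viterbi <- function(log_emis, chain) {
  log_emis <- as.matrix(log_emis)
  n <- nrow(log_emis); J <- ncol(log_emis)
  logP <- log(chain$trans)
  delta <- log(chain$init) + log_emis[1L, ]
  back <- matrix(0L, n, J)
  for (k in seq_len(n)[-1L]) {
    cand <- delta + logP             # cand[i, j] = delta_i + log P_ij
    back[k, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(back[k, ], seq_len(J))] + log_emis[k, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) for (k in (n - 1L):1L) path[k] <- back[k + 1L, path[k + 1L]]
  path
}
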