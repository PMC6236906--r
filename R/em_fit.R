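# Generalized EM estimation.
#
# E-step: scaled forward-backward posteriors. M-step: closed-form updates
# for the chain parameters (initial probabilities and transition rows are
# normalized expected counts) and a box-constrained L-BFGS-B maximization
# of the expected emission term Q_theta over the global parameters
# (purity, ploidy, scales, t degrees of freedom). The inner optimizer is
# run for a bounded number of iterations per M-step: any improvement of
# Q_theta preserves the generalized-EM monotone-likelihood guarantee, and
# full inner convergence every iteration buys nothing.

#' Box constraints for the global parameters
#'
#' Default parameter box: purity in \[0.01, 0.99\], ploidy in \[0.5, 8\],
#' variance components in \[1e-6, 100\], t degrees of freedom in
#' \[2.1, 100\] (keeping every density proper and the t variance finite).
#'
#' @param family `"t"` or `"normal"`.
#' @return List with `lower` and `upper` named vectors.
#' @export
default_bounds <- function(family = c("t", "normal")) {
  family <- match.arg(family)
  lower <- c(purity = 0.01, ploidy = 0.5, logR_scale2 = 1e-6,
             logOR_scale2 = 1e-6)
  upper <- c(purity = 0.99, ploidy = 8, logR_scale2 = 100,
             logOR_scale2 = 100)
  if (family == "t") {
    lower <- c(lower, df = 2.1)
    upper <- c(upper, df = 100)
  }
  list(lower = lower, upper = upper)
}

pack_globals <- function(globals) {
  th <- c(purity = globals$purity, ploidy = globals$ploidy,
          logR_scale2 = globals$logR_scale2,
          logOR_scale2 = globals$logOR_scale2)
  if (globals$family == "t") th <- c(th, df = globals$df)
  th
}

unpack_globals <- function(theta, family) {
  structure(list(purity = theta[["purity"]], ploidy = theta[["ploidy"]],
                 logR_scale2 = theta[["logR_scale2"]],
                 logOR_scale2 = theta[["logOR_scale2"]],
                 df = if (family == "t") theta[["df"]] else NULL,
                 family = family),
            class = "global_params")
}

#' Chain-parameter M-step
#'
#' Closed-form maximizers of the initial-probability and transition terms
#' of the expected complete-data log-likelihood: \eqn{\hat r_{0j} =
#' \gamma_{1j} / \sum_l \gamma_{1l}} and \eqn{\hat P_{ij} = \sum_k
#' \eta_k^{i,j} / \sum_k \sum_l \eta_k^{i,l}}. A state with zero expected
#' visits gets a uniform transition row (regularization; its row carries
#' no information).
#'
#' @param posterior An `hmm_posterior` from [hmm_posteriors()].
#' @return A [chain_params] object.
#' @export
m_step_chain <- function(posterior) {
  g1 <- posterior$gamma1
  init <- g1 / sum(g1)
  ps <- posterior$pair_sums
  J <- nrow(ps)
  rs <- rowSums(ps)
  trans <- matrix(1 / J, J, J)
  ok <- rs > 0
  trans[ok, ] <- ps[ok, , drop = FALSE] / rs[ok]
  chain_params(init, trans)
}

#' Expected emission term of the EM objective
#'
#' \eqn{Q_\theta = \sum_k \sum_j \gamma_{kj} \log p(W_k, X_k^2 \mid Z_k =
#' j)}: the posterior-weighted log emission, the piece of the expected
#' complete-data log-likelihood that depends on the global parameters.
#'
#' @param globals A [global_params] object.
#' @param gamma N x J matrix of state posteriors.
#' @param loci Data frame of loci (`logR`, `logOR`, `het`).
#' @param space A `state_space`.
#' @param bounds Optional box constraints; parameters outside the box are
#'   an error.
#' @return Scalar value of \eqn{Q_\theta}.
#' @export
q_theta <- function(globals, gamma, loci, space,
                    bounds = default_bounds(globals$family)) {
  th <- pack_globals(globals)
  if (any(th < bounds$lower - 1e-12) || any(th > bounds$upper + 1e-12))
    stop("global parameters outside the box constraints: ",
         paste(names(th)[th < bounds$lower | th > bounds$upper],
               collapse = ", "))
  sum(gamma * emission_log_matrix(loci, space, globals))
}

# Analytic gradient of Q_theta with respect to the packed global
# parameter vector. The logR term is the location-scale t (or normal)
# log-density differentiated through mu_j(alpha, psi); the logOR^2 term
# uses the folded-normal form of the noncentral chi-square density,
# f(y) = [phi((s-zeta)/tau) + phi((s+zeta)/tau)] / (2 s tau), s = sqrt(y),
# which is the same function as dchisq(y/tau^2, 1, zeta^2/tau^2)/tau^2
# but differentiates cleanly in zeta and tau^2.
q_theta_grad <- function(theta, gamma, loci, space, family) {
  a <- theta[["purity"]]; psi <- theta[["ploidy"]]
  k2 <- theta[["logR_scale2"]]; tau2 <- theta[["logOR_scale2"]]
  cn <- normal_cn_of(space)
  mu <- expected_logR(space, a, psi, cn)
  zeta <- expected_logOR(space, a)
  dmu_da <- (space$total_cn - cn) / (log(2) * ((1 - a) * cn + a * space$total_cn))
  dmu_dpsi <- -1 / (psi * log(2))
  m <- space$major_cn; p <- space$minor_cn
  dzeta_da <- (m - 1) / ((1 - a) + a * m) - (p - 1) / ((1 - a) + a * p)
  het <- which(loci$het)
  s <- sqrt(pmax(loci$logOR[het]^2, 1e-12))
  gH <- gamma[het, , drop = FALSE]
  J <- nrow(space)
  g_a <- g_psi <- g_k2 <- g_tau2 <- g_v <- 0
  if (family == "t") v <- theta[["df"]]
  for (j in seq_len(J)) {
    r <- loci$logR - mu[j]
    gj <- gamma[, j]
    if (family == "t") {
      denom <- v * k2 + r^2
      dl_dmu <- (v + 1) * r / denom
      g_k2 <- g_k2 + sum(gj * (-1 / (2 * k2) +
                                 (v + 1) / 2 * r^2 / (k2 * denom)))
      g_v <- g_v + sum(gj * (0.5 * digamma((v + 1) / 2) -
                               0.5 * digamma(v / 2) - 1 / (2 * v) -
                               0.5 * log1p(r^2 / (v * k2)) +
                               (v + 1) / 2 * r^2 / (v * denom)))
    } else {
      dl_dmu <- r / k2
      g_k2 <- g_k2 + sum(gj * (-1 / (2 * k2) + r^2 / (2 * k2^2)))
    }
    g_a <- g_a + sum(gj * dl_dmu) * dmu_da[j]
    g_psi <- g_psi + sum(gj * dl_dmu) * dmu_dpsi
    if (length(het)) {
      d1 <- (s - zeta[j])^2 / (2 * tau2)
      d2 <- (s + zeta[j])^2 / (2 * tau2)
      dmin <- pmin(d1, d2)
      w1 <- exp(-(d1 - dmin)); w2 <- exp(-(d2 - dmin))
      wsum <- w1 + w2
      dlf_dzeta <- (w1 * (s - zeta[j]) - w2 * (s + zeta[j])) / (tau2 * wsum)
      dlf_dtau2 <- -1 / (2 * tau2) +
        (w1 * (s - zeta[j])^2 + w2 * (s + zeta[j])^2) / (2 * tau2^2 * wsum)
      gHj <- gH[, j]
      g_a <- g_a + sum(gHj * dlf_dzeta) * dzeta_da[j]
      g_tau2 <- g_tau2 + sum(gHj * dlf_dtau2)
    }
  }
  out <- c(purity = g_a, ploidy = g_psi, logR_scale2 = g_k2,
           logOR_scale2 = g_tau2)
  if (family == "t") out <- c(out, df = g_v)
  out
}

#' Global-parameter M-step
#'
#' Box-constrained quasi-Newton (L-BFGS-B) ascent of [q_theta()] from
#' `start`. Returns parameters satisfying the generalized-EM contract
#' `q_theta(new) >= q_theta(start) - 1e-9`; on optimizer failure the start
#' is returned unchanged with a warning, which preserves monotone ascent.
#'
#' @inheritParams q_theta
#' @param start A [global_params] object inside `bounds`.
#' @param control Passed to [stats::optim()]; the default caps inner
#'   iterations at 25 (any inner improvement suffices for generalized EM).
#' @return A [global_params] object.
#' @export
m_step_global <- function(gamma, loci, space, start,
                          bounds = default_bounds(start$family),
                          control = list(maxit = 25)) {
  family <- start$family
  th0 <- pack_globals(start)
  negq <- function(th) {
    -sum(gamma * emission_log_matrix(loci, space, unpack_globals(th, family)))
  }
  neggrad <- function(th) -q_theta_grad(th, gamma, loci, space, family)
  q0 <- -negq(th0)
  opt <- tryCatch(
    stats::optim(th0, negq, gr = neggrad, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = control),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || -opt$value < q0 - 1e-9) {
    if (is.null(opt) || !is.finite(opt$value))
      warning("global M-step optimizer failed; keeping current parameters")
    return(start)
  }
  unpack_globals(opt$par, family)
}

#' AIC and BIC
#'
#' Standard information criteria. The parameter count includes the chain:
#' J-1 free initial probabilities, J(J-1) free transition entries, plus
#' the global parameters (5 for the t family, 4 for the normal family).
#'
#' @param loglik Maximized observed-data log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_obs Number of loci.
#' @return List with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  stopifnot(n_params >= 1, n_obs >= 1)
  list(aic = -2 * loglik + 2 * n_params,
       bic = -2 * loglik + log(n_obs) * n_params)
}

#' Count free parameters of a model
#'
#' @param J Number of genotype states.
#' @param family Emission family.
#' @return Integer count: (J-1) + J(J-1) + 5 (t) or 4 (normal).
#' @export
count_params <- function(J, family = c("t", "normal")) {
  family <- match.arg(family)
  (J - 1L) + J * (J - 1L) + if (family == "t") 5L else 4L
}

validate_loci <- function(loci) {
  need <- c("logR", "het")
  if (!all(need %in% names(loci)))
    stop("loci must have columns logR and het (plus logOR for heterozygous loci)")
  if (!"logOR" %in% names(loci)) loci$logOR <- NA_real_
  if (any(!is.finite(loci$logR)))
    stop("non-finite logR at loci: ",
         paste(utils::head(which(!is.finite(loci$logR))), collapse = ", "))
  if (any(loci$het & !is.finite(loci$logOR)))
    stop("heterozygous loci must carry a finite logOR")
  loci$het <- as.logical(loci$het)
  loci
}

moment_start <- function(loci, purity, ploidy, family, bounds) {
  # robust spread of logR around its running location; MAD is immune to
  # the outliers the t family is there for
  s2 <- stats::mad(loci$logR)^2
  if (!is.finite(s2) || s2 <= 0) s2 <- stats::var(loci$logR)
  if (!is.finite(s2) || s2 <= 0) s2 <- 0.25
  x2 <- loci$logOR[loci$het]^2
  tau2 <- if (length(x2)) stats::median(x2) else 0.5
  clamp <- function(v, nm) min(max(v, bounds$lower[[nm]]), bounds$upper[[nm]])
  if (family == "t") {
    df0 <- 5
    global_params(purity, ploidy,
                  clamp(s2 * (df0 - 2) / df0, "logR_scale2"),
                  clamp(tau2, "logOR_scale2"), df = df0, family = "t")
  } else {
    global_params(purity, ploidy, clamp(s2, "logR_scale2"),
                  clamp(tau2, "logOR_scale2"), family = "normal")
  }
}

em_iterate <- function(loci, space, globals, chain, bounds, n_iter, tol,
                       trace = numeric(0), m_control = list(maxit = 25)) {
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    le <- emission_log_matrix(loci, space, globals)
    post <- hmm_posteriors(le, chain)
    ll <- post$loglik
    if (!is.finite(ll))
      stop("non-finite log-likelihood at EM iteration ", length(trace) + 1L)
    if (length(trace) &&
        abs(ll - trace[length(trace)]) < tol * (abs(trace[length(trace)]) + 1e-3)) {
      trace <- c(trace, ll)
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    chain <- m_step_chain(post)
    globals <- m_step_global(post$gamma, loci, space, globals,
                             bounds = bounds, control = m_control)
  }
  # refresh the posterior at the final parameters
  le <- emission_log_matrix(loci, space, globals)
  post <- hmm_posteriors(le, chain)
  list(globals = globals, chain = chain, posterior = post,
       trace = trace, converged = converged)
}

#' Fit the allele-specific copy number HMM
#'
#' Full EM driver: alternates scaled forward-backward posteriors (E-step)
#' with the closed-form chain update and the box-constrained global update
#' (M-step) until the relative log-likelihood change drops below `tol` or
#' `max_iter` is reached. The purity/ploidy likelihood surface is
#' multimodal, so by default a coarse grid of starts (ploidy 1.5/2/3/4 x
#' purity 0.3/0.6/0.9, robust moment starts for the scales, df = 5) is
#' screened with a few EM iterations each and the best-scoring start is
#' run to convergence.
#'
#' @param loci Data frame with columns `logR`, `logOR` (NA at homozygous
#'   loci), `het` (logical), and optionally `chrom`, `pos`.
#' @param space A `state_space`; default the 12-state space.
#' @param family Emission family for logR: `"t"` (heavy-tailed, default)
#'   or `"normal"`.
#' @param init Optional [global_params] start; overrides the grid.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param screen_iters EM iterations used to screen each grid start
#'   (default 3); ignored when `init` is given.
#' @param chain_init Optional [chain_params] start; default uniform
#'   initial probabilities with sticky (0.99 self-transition) transitions.
#' @param bounds Box constraints, default [default_bounds()].
#' @param compute_se If `TRUE`, fill `se` via [standard_errors()].
#' @return An `ascn_fit` object: `globals`, `chain`, `posterior`,
#'   `decoded` (per-locus state index/label/copy numbers and posterior
#'   maximum), `loglik`, `loglik_trace`, `converged`, `n_params`, `aic`,
#'   `bic`, `se`.
#' @export
fit_ascn_hmm <- function(loci, space = genotype_states(),
                         family = c("t", "normal"), init = NULL,
                         tol = 1e-6, max_iter = 500L, screen_iters = 3L,
                         chain_init = NULL, bounds = NULL,
                         compute_se = FALSE) {
  family <- match.arg(family)
  loci <- validate_loci(loci)
  stopifnot(nrow(loci) >= 2)
  J <- nrow(space)
  if (is.null(bounds)) bounds <- default_bounds(family)
  if (is.null(chain_init)) chain_init <- sticky_chain(J)

  best <- if (!is.null(init)) {
    list(globals = init, chain = chain_init, trace = numeric(0))
  } else {
    # rank the full grid by the likelihood at the start (one forward pass
    # each), then give the leaders a short EM burst; the winner by final
    # log-likelihood is run to convergence below
    grid <- expand.grid(ploidy = c(1.5, 2, 3, 4), purity = c(0.3, 0.6, 0.9))
    cand <- lapply(seq_len(nrow(grid)), function(i)
      moment_start(loci, grid$purity[i], grid$ploidy[i], family, bounds))
    ll0 <- vapply(cand, function(g)
      forward_scaled(emission_log_matrix(loci, space, g), chain_init)$loglik,
      numeric(1))
    top <- order(ll0, decreasing = TRUE)[seq_len(min(4L, length(cand)))]
    bursts <- lapply(top, function(i) {
      st <- em_iterate(loci, space, cand[[i]], chain_init, bounds,
                       n_iter = screen_iters, tol = tol)
      list(globals = st$globals, chain = st$chain, trace = st$trace)
    })
    bursts[[which.max(vapply(bursts, function(s) s$trace[length(s$trace)],
                             numeric(1)))]]
  }

  res <- em_iterate(loci, space, best$globals, best$chain, bounds,
                    n_iter = max_iter - length(best$trace), tol = tol,
                    trace = best$trace)

  gamma <- res$posterior$gamma
  idx <- decode_map(gamma)
  decoded <- data.frame(
    state_index = idx,
    label = space$label[idx],
    total_cn = space$total_cn[idx],
    major_cn = space$major_cn[idx],
    minor_cn = space$minor_cn[idx],
    posterior = gamma[cbind(seq_along(idx), idx)],
    stringsAsFactors = FALSE
  )
  if (all(c("chrom", "pos") %in% names(loci)))
    decoded <- cbind(loci[, c("chrom", "pos")], decoded)

  n_params <- count_params(J, family)
  ic <- information_criteria(res$posterior$loglik, n_params, nrow(loci))
  fit <- structure(list(
    globals = res$globals, chain = res$chain, posterior = res$posterior,
    decoded = decoded, loglik = res$posterior$loglik,
    loglik_trace = res$trace, converged = res$converged,
    n_iter = length(res$trace), n_params = n_params,
    aic = ic$aic, bic = ic$bic, family = family, space = space,
    bounds = bounds, se = NULL, loci = loci
  ), class = "ascn_fit")
  if (compute_se) fit$se <- standard_errors(fit, loci, space)
  fit
}

#' @export
print.ascn_fit <- function(x, ...) {
  g <- x$globals
  cat(sprintf(
    "Allele-specific copy number HMM fit (%s family, %d states)\n",
    x$family, nrow(x$space)))
  cat(sprintf("  purity %.3f  ploidy %.3f  logR scale^2 %.4f  logOR var %.4f%s\n",
              g$purity, g$ploidy, g$logR_scale2, g$logOR_scale2,
              if (g$family == "t") sprintf("  df %.2f", g$df) else ""))
  cat(sprintf("  loglik %.2f  AIC %.2f  BIC %.2f  (%d EM iterations%s)\n",
              x$loglik, x$aic, x$bic, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

# Central-difference Hessian; step relative to parameter magnitude.
num_hessian <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(abs(x), 1e-2)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1L):p) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Hessian-based standard errors for the global parameters
#'
#' Asymptotic standard errors: square roots of the diagonal of the inverse
#' numeric Hessian of the negative observed-data log-likelihood with
#' respect to the global parameters, the chain parameters held fixed at
#' their estimates (profile Hessian). A non-invertible or non-positive
#' Hessian yields `NA` SEs — never fabricated values.
#'
#' @param fit An `ascn_fit`.
#' @param loci The loci the fit was computed on (default: stored in the
#'   fit).
#' @param space State space (default: stored in the fit).
#' @return Named numeric vector of SEs (NA where unavailable).
#' @export
standard_errors <- function(fit, loci = fit$loci, space = fit$space) {
  family <- fit$family
  chain <- fit$chain
  th <- pack_globals(fit$globals)
  negll <- function(theta) {
    g <- unpack_globals(theta, family)
    if (g$purity <= 0 || g$purity >= 1 || g$ploidy <= 0 ||
        g$logR_scale2 <= 0 || g$logOR_scale2 <= 0 ||
        (family == "t" && g$df <= 2)) return(NA_real_)
    -forward_scaled(emission_log_matrix(loci, space, g), chain)$loglik
  }
  H <- tryCatch(num_hessian(negll, th), error = function(e) NULL)
  se <- rep(NA_real_, length(th))
  names(se) <- names(th)
  if (!is.null(H) && all(is.finite(H))) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      d <- diag(Hi)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }
  if (anyNA(se))
    warning("Hessian not (fully) invertible; ",
            sum(is.na(se)), " standard error(s) unavailable")
  se
}
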