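# Per-locus, per-state joint log emission densities for (logR, logOR^2).
#
# logR: Student-t (heavy-tailed, robust to the outliers that drive
# hypersegmentation) or normal. The t density is the analytic closed form
# of the normal-gamma scale mixture
#   t_v(w | mu, kappa^2) = \int N(w | mu, kappa^2/u) Gamma(u; v/2, v/2) du,
# integrated out exactly; the mixture form survives only as a test oracle.
#
# logOR^2: X^2 / tau^2 ~ noncentral chi-square, df 1, noncentrality
# delta = zeta^2 / tau^2 (equivalently X ~ N(zeta, tau^2) up to sign, which
# squaring discards). The -log(tau^2) change-of-variable constant is
# included so the log-likelihood (hence AIC/BIC) is a valid function of
# tau^2; it does not affect state posteriors at fixed tau^2.

#' Log-density floor: emissions below this are clamped so that -Inf never
#' enters the forward-backward recursions (exp(-745) is the smallest
#' positive normalized double).
#' @export
EMIT_LOG_FLOOR <- -745

#' Student-t log-density for logR
#'
#' Location-scale t density with location `mu`, squared scale `scale2` and
#' `df` degrees of freedom (variance `scale2 * df/(df-2)` for `df > 2`).
#'
#' @param w Observed logR value(s).
#' @param mu Location (expected logR of the state).
#' @param scale2 Squared scale \eqn{\kappa^2 > 0}.
#' @param df Degrees of freedom \eqn{v > 0}.
#' @return Log-density, vectorized over `w`.
#' @export
dlogr_t <- function(w, mu, scale2, df) {
  stopifnot(scale2 > 0, df > 0)
  stats::dt((w - mu) / sqrt(scale2), df = df, log = TRUE) - 0.5 * log(scale2)
}

#' Normal log-density for logR
#' @inheritParams dlogr_t
#' @param var Variance \eqn{\sigma^2 > 0}.
#' @export
dlogr_norm <- function(w, mu, var) {
  stopifnot(var > 0)
  stats::dnorm(w, mean = mu, sd = sqrt(var), log = TRUE)
}

#' Log-density of squared logOR
#'
#' Density of the observed \eqn{X^2} under \eqn{X^2/\tau^2 \sim
#' \chi^2_1(\delta)} with noncentrality \eqn{\delta = \zeta^2/\tau^2},
#' including the \eqn{-\log\tau^2} Jacobian so values are comparable
#' across \eqn{\tau^2}.
#'
#' @param x2 Observed squared logOR (non-negative).
#' @param zeta Expected logOR \eqn{\zeta_j} of the state.
#' @param tau2 logOR variance \eqn{\tau^2 > 0}.
#' @return Log-density, vectorized over `x2`.
#' @export
dlogor_sq <- function(x2, zeta, tau2) {
  stopifnot(tau2 > 0)
  if (any(x2 < 0, na.rm = TRUE)) stop("squared logOR must be non-negative")
  stats::dchisq(x2 / tau2, df = 1, ncp = zeta^2 / tau2, log = TRUE) - log(tau2)
}

#' Global emission parameters
#'
#' Container for the parameters shared across loci: tumor purity
#' \eqn{\alpha}, ploidy \eqn{\psi}, logR squared scale (\eqn{\kappa^2} for
#' the t family; the variance \eqn{\sigma^2} for the normal family), logOR
#' variance \eqn{\tau^2}, and for the t family the degrees of freedom
#' \eqn{v > 2} (so the logR variance \eqn{\kappa^2 v/(v-2)} is finite).
#'
#' @param purity Tumor purity in (0, 1).
#' @param ploidy Tumor ploidy, positive.
#' @param logR_scale2 \eqn{\kappa^2} (t) or \eqn{\sigma^2} (normal), positive.
#' @param logOR_scale2 \eqn{\tau^2}, positive.
#' @param df Degrees of freedom (t family only), must exceed 2.
#' @param family `"t"` or `"normal"`.
#' @return A `global_params` list.
#' @export
global_params <- function(purity, ploidy, logR_scale2, logOR_scale2,
                          df = NULL, family = c("t", "normal")) {
  family <- match.arg(family)
  stopifnot(purity > 0, purity < 1, ploidy > 0,
            logR_scale2 > 0, logOR_scale2 > 0)
  if (family == "t") {
    if (is.null(df) || df <= 2)
      stop("t family requires df > 2 (finite logR variance)")
  } else {
    df <- NULL
  }
  structure(list(purity = purity, ploidy = ploidy,
                 logR_scale2 = logR_scale2, logOR_scale2 = logOR_scale2,
                 df = df, family = family),
            class = "global_params")
}

#' @export
print.global_params <- function(x, ...) {
  cat(sprintf("global_params [%s family]: purity=%.4g ploidy=%.4g logR_scale2=%.4g logOR_scale2=%.4g%s\n",
              x$family, x$purity, x$ploidy, x$logR_scale2, x$logOR_scale2,
              if (x$family == "t") sprintf(" df=%.4g", x$df) else ""))
  invisible(x)
}

#' Joint log emission of one locus under one state
#'
#' Sum of the logR log-density (family per `params$family`, located at the
#' state's expected logR) and, if and only if the locus is heterozygous,
#' the squared-logOR log-density with noncentrality set by the state's
#' expected logOR. At homozygous loci logOR is missing and the emission is
#' the logR term alone — missingness is modeled, never imputed.
#'
#' @param obs A single locus: list/row with `logR`, `logOR` (may be `NA`)
#'   and `het` (logical).
#' @param state A single state: row of a `state_space`.
#' @param params A [global_params] object.
#' @param space The `state_space` the state belongs to (source of the
#'   normal copy number).
#' @return Scalar log emission density.
#' @export
joint_log_emission <- function(obs, state, params, space) {
  mu <- expected_logR(state, params$purity, params$ploidy,
                      normal_cn = normal_cn_of(space))
  ll <- if (params$family == "t") {
    dlogr_t(obs$logR, mu, params$logR_scale2, params$df)
  } else {
    dlogr_norm(obs$logR, mu, params$logR_scale2)
  }
  if (isTRUE(obs$het)) {
    zeta <- expected_logOR(state, params$purity)
    ll <- ll + dlogor_sq(obs$logOR^2, zeta, params$logOR_scale2)
  }
  max(ll, EMIT_LOG_FLOOR)
}

#' Emission log-density matrix
#'
#' Vectorized joint log emission over all loci and states: entry (k, j) is
#' the log emission of locus k under state j, floored at [EMIT_LOG_FLOOR]
#' so every entry is finite.
#'
#' @param loci Data frame of loci with columns `logR`, `logOR`, `het`.
#' @param space A `state_space`.
#' @param params A [global_params] object.
#' @return N x J numeric matrix of finite log emissions.
#' @export
emission_log_matrix <- function(loci, space, params) {
  n <- nrow(loci)
  J <- nrow(space)
  stopifnot(n >= 1, J >= 1)
  mu <- expected_logR(space, params$purity, params$ploidy)
  zeta <- expected_logOR(space, params$purity)
  het <- which(loci$het)
  # chi-square(1) density diverges at 0 uniformly in the state; clamping
  # keeps the matrix finite without touching state contrasts
  x2 <- pmax(loci$logOR[het]^2, 1e-12)
  out <- matrix(0, n, J)
  for (j in seq_len(J)) {
    col <- if (params$family == "t") {
      dlogr_t(loci$logR, mu[j], params$logR_scale2, params$df)
    } else {
      dlogr_norm(loci$logR, mu[j], params$logR_scale2)
    }
    if (length(het)) {
      col[het] <- col[het] + dlogor_sq(x2, zeta[j], params$logOR_scale2)
    }
    out[, j] <- col
  }
  out[out < EMIT_LOG_FLOOR | is.na(out)] <- EMIT_LOG_FLOOR
  out
}
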