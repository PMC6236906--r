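# Simulators with known ground truth.
#
# Three designs: (1) t-distributed logR noise, the model's own world;
# (2) a two-component normal mixture for logR noise, a long-tailed world
# the t family does not match exactly (robustness check); (3) raw paired
# tumor/normal read counts with uniform or skewed (beta) depth variation,
# from which logR/logOR are computed the same way as for real count data.
# In designs 1-2 observed logOR is zeta_j + normal noise, so the squared
# value is tau^2 times a noncentral chi-square draw, exactly the emission
# model. The truth transition matrix defaults to a sticky chain
# (self-transition 0.995), which yields long segments.

#' Simulation configuration
#'
#' Captures every knob of the three simulation designs; unspecified
#' arguments take the benchmark defaults (purity 0.9, ploidy 1.6, logR
#' squared scale 0.3 with 4 t degrees of freedom, logOR variance 0.5, 90\%
#' homozygous loci, sticky truth chain with self-transition 0.995).
#'
#' @param scenario `"t_logR"`, `"mixnorm_logR"` or `"read_counts"`.
#' @param n_loci Number of loci (designs 1-2; design 3 derives it from
#'   `segment_lengths`).
#' @param states_true Genotype labels of the truth states.
#' @param trans_true Row-stochastic truth transition matrix (designs 1-2).
#' @param purity,ploidy Truth purity \eqn{\alpha} and ploidy \eqn{\psi}.
#' @param logR_scale2 \eqn{\kappa^2}, squared scale of the t logR noise.
#' @param df t degrees of freedom \eqn{v}.
#' @param logOR_err_var \eqn{\tau^2}, variance of the additive logOR noise.
#' @param frac_homozygous Fraction of loci without logOR.
#' @param mixnorm Design-2 noise: list `pi` (two mixture weights summing
#'   to 1), `mean` (component means with `sum(pi*mean) == 0`), `var`
#'   (component variances). Default weights `(0.7, 0.3)`, means 0,
#'   variances `(0.5, 4.5)`, so the total error variance is
#'   `0.7*0.5 + 0.3*4.5 = 1.7`.
#' @param segment_lengths Design-3 loci per segment for the cycling
#'   A, AB, AA truth profile; default `c(1600, 1800, 1542)` (4942 loci).
#' @param normal_depth,tumor_depth Design-3 nominal coverages (40, 160).
#' @param skewed_depth If `TRUE`, design-3 depths are drawn from a
#'   beta(1, 6) rescaled to \[1, 2 x nominal\] instead of uniform bands.
#' @return A `sim_config` list.
#' @export
sim_config <- function(scenario = c("t_logR", "mixnorm_logR", "read_counts"),
                       n_loci = 10000L,
                       states_true = c("A", "AA", "AAAB", "AAAAB"),
                       trans_true = NULL,
                       purity = 0.9, ploidy = 1.6,
                       logR_scale2 = 0.3, df = 4,
                       logOR_err_var = 0.5, frac_homozygous = 0.9,
                       mixnorm = list(pi = c(0.7, 0.3), mean = c(0, 0),
                                      var = c(0.5, 0.5 * 3^2)),
                       segment_lengths = c(1600L, 1800L, 1542L),
                       normal_depth = 40, tumor_depth = 160,
                       skewed_depth = FALSE) {
  scenario <- match.arg(scenario)
  if (scenario == "read_counts") states_true <- c("A", "AB", "AA")
  J <- length(states_true)
  if (is.null(trans_true)) trans_true <- sticky_chain(J, self = 0.995)$trans
  stopifnot(frac_homozygous >= 0, frac_homozygous <= 1)
  if (abs(sum(mixnorm$pi) - 1) > 1e-8)
    stop("mixnorm mixture weights must sum to 1")
  if (abs(sum(mixnorm$pi * mixnorm$mean)) > 1e-8)
    stop("mixnorm component means must satisfy E(eps) = 0")
  structure(list(scenario = scenario, n_loci = as.integer(n_loci),
                 states_true = states_true, trans_true = trans_true,
                 purity = purity, ploidy = ploidy,
                 logR_scale2 = logR_scale2, df = df,
                 logOR_err_var = logOR_err_var,
                 frac_homozygous = frac_homozygous, mixnorm = mixnorm,
                 segment_lengths = as.integer(segment_lengths),
                 normal_depth = normal_depth, tumor_depth = tumor_depth,
                 skewed_depth = skewed_depth),
            class = "sim_config")
}

#' Sample a genotype state sequence from a Markov chain
#'
#' @param trans J x J row-stochastic transition matrix.
#' @param n Sequence length.
#' @param init Initial distribution (default uniform).
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer vector of 1-based state indices.
#' @export
sim_genotype_chain <- function(trans, n, init = NULL, seed = NULL) {
  trans <- as.matrix(trans)
  J <- nrow(trans)
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  if (is.null(init)) init <- rep(1 / J, J)
  if (!is.null(seed)) set.seed(seed)
  z <- integer(n)
  z[1L] <- sample.int(J, 1L, prob = init)
  # one uniform per step, inverted through the row CDF
  u <- stats::runif(n - 1L)
  cdf <- t(apply(trans, 1, cumsum))
  for (k in seq_len(n - 1L)) {
    z[k + 1L] <- findInterval(u[k], cdf[z[k], ]) + 1L
  }
  z
}

sim_observe <- function(z, space, config, eps_logR) {
  n <- length(z)
  mu <- expected_logR(space, config$purity, config$ploidy)
  zeta <- expected_logOR(space, config$purity)
  logR <- mu[z] + eps_logR
  het <- rep(FALSE, n)
  n_het <- round(n * (1 - config$frac_homozygous))
  het[sample.int(n, n_het)] <- TRUE
  logOR <- rep(NA_real_, n)
  logOR[het] <- zeta[z[het]] +
    stats::rnorm(sum(het), 0, sqrt(config$logOR_err_var))
  data.frame(chrom = "1", pos = seq_len(n), logR = logR, logOR = logOR,
             het = het, stringsAsFactors = FALSE)
}

new_sim_dataset <- function(loci, truth, space, config) {
  structure(list(loci = loci, truth = truth, space = space,
                 config = config), class = "sim_dataset")
}

#' Design 1: t-distributed logR
#'
#' Truth states over `config$states_true` from the sticky Markov chain;
#' logR is the state's expectation plus \eqn{\kappa \cdot t_v} noise
#' (variance \eqn{\kappa^2 v/(v-2)}); heterozygous loci (fraction
#' `1 - frac_homozygous`, placed uniformly at random) observe logOR as
#' the state's expectation plus normal noise of variance \eqn{\tau^2}.
#'
#' @param config A [sim_config()] with `scenario = "t_logR"`.
#' @param seed Optional RNG seed.
#' @return A `sim_dataset`: `loci` (data frame), `truth` (state indices),
#'   `space` (the truth `state_space`), `config`.
#' @export
sim_scenario_t <- function(config = sim_config("t_logR"), seed = NULL) {
  stopifnot(config$scenario == "t_logR")
  if (!is.null(seed)) set.seed(seed)
  space <- genotype_states(config$states_true)
  z <- sim_genotype_chain(config$trans_true, config$n_loci)
  eps <- sqrt(config$logR_scale2) * stats::rt(config$n_loci, df = config$df)
  new_sim_dataset(sim_observe(z, space, config, eps), z, space, config)
}

#' Design 2: normal-mixture logR
#'
#' As design 1, but the logR noise is a two-component normal mixture
#' (default 0.7/0.3 with variances 0.5 and 4.5: mean 0, total variance
#' 1.7) — long-tailed but not t, probing robustness to emission
#' misspecification.
#'
#' @param config A [sim_config()] with `scenario = "mixnorm_logR"`.
#' @inheritParams sim_scenario_t
#' @export
sim_scenario_mixnorm <- function(config = sim_config("mixnorm_logR"),
                                 seed = NULL) {
  stopifnot(config$scenario == "mixnorm_logR")
  if (!is.null(seed)) set.seed(seed)
  space <- genotype_states(config$states_true)
  z <- sim_genotype_chain(config$trans_true, config$n_loci)
  mx <- config$mixnorm
  comp <- sample.int(length(mx$pi), config$n_loci, replace = TRUE,
                     prob = mx$pi)
  eps <- stats::rnorm(config$n_loci, mx$mean[comp], sqrt(mx$var[comp]))
  new_sim_dataset(sim_observe(z, space, config, eps), z, space, config)
}

# Depth/count draw around a center: uniform band center +/- hw, or a
# beta(1, 6) draw rescaled to [1, 2*center] in skewed mode; values < 1
# are redrawn so every retained depth is a positive integer.
draw_depth <- function(n, center, hw, skewed) {
  draw <- function(m) {
    if (skewed) 1 + (2 * center - 1) * stats::rbeta(m, 1, 6)
    else stats::runif(m, center - hw, center + hw)
  }
  x <- round(draw(n))
  bad <- x < 1
  while (any(bad)) {
    x[bad] <- round(draw(sum(bad)))
    bad <- x < 1
  }
  x
}

# Joint draw of an allele count (center c_count, band hw) and a depth
# (center c_depth); independently drawn pairs violating 0 <= count <=
# depth are redrawn, so no probability mass piles up at ref = 0.
draw_count_depth <- function(n, c_count, c_depth, hw, skewed) {
  depth <- draw_depth(n, c_depth, hw, skewed)
  count <- round(stats::runif(n, c_count - hw, c_count + hw))
  bad <- count < 0 | count > depth
  while (any(bad)) {
    depth[bad] <- draw_depth(sum(bad), c_depth, hw, skewed)
    count[bad] <- round(stats::runif(sum(bad), c_count - hw, c_count + hw))
    bad <- count < 0 | count > depth
  }
  list(count = count, depth = depth)
}

#' Design 3: read-count-based simulation
#'
#' Generates raw paired tumor/normal allele counts without using the
#' emission model at all. The truth profile cycles A, AB, AA in segments
#' of `config$segment_lengths` loci. Normal tissue: depth 40 with allele-A
#' count 20 at heterozygous germline loci (truth A and AB) and 40 at
#' homozygous loci (truth AA), jittered by uniform bands of half-width 15
#' (AA, AB) or 20 (A). Tumor tissue: count/depth centers 80/160 (AB),
#' 160/160 (AA) and 80/80 (A — the B allele is lost, so the count equals
#' the depth at half the nominal coverage), jittered by a 70/30 mixture of
#' uniform bands of half-width 30 and 15. All counts are rounded to
#' integers; depths below 1 are redrawn. logR and logOR are then computed
#' from the counts via [compute_logR()] and [compute_logOR()].
#'
#' @param config A [sim_config()] with `scenario = "read_counts"`.
#' @inheritParams sim_scenario_t
#' @return A `sim_dataset` whose `loci` carry the computed logR/logOR and
#'   whose `counts` element holds the raw count table.
#' @export
sim_read_counts <- function(config = sim_config("read_counts"),
                            seed = NULL) {
  stopifnot(config$scenario == "read_counts")
  if (!is.null(seed)) set.seed(seed)
  space <- genotype_states(config$states_true)  # A, AB, AA
  segs <- config$segment_lengths
  z <- rep(rep_len(seq_along(segs), length(segs)), segs)
  n <- length(z)
  lab <- config$states_true[z]
  sk <- config$skewed_depth
  nd <- config$normal_depth; td <- config$tumor_depth

  n_hw <- ifelse(lab == "A", 20, 15)
  normal_depth <- integer(n); normal_alt <- integer(n)
  tumor_depth <- integer(n); tumor_alt <- integer(n)
  # mixture of measurement-error bands for tumor draws
  t_hw <- ifelse(stats::runif(n) < 0.7, 30, 15)
  for (g in unique(lab)) {
    i <- which(lab == g)
    hw <- n_hw[i][1]
    if (g == "AA") {            # homozygous germline: count == depth
      normal_depth[i] <- draw_depth(length(i), nd, hw, sk)
      normal_alt[i] <- normal_depth[i]
    } else {                    # heterozygous germline: count ~ depth/2
      dc <- draw_count_depth(length(i), nd / 2, nd, hw, sk)
      normal_depth[i] <- dc$depth
      normal_alt[i] <- dc$count
    }
    for (band in unique(t_hw[i])) {
      ii <- i[t_hw[i] == band]
      m <- length(ii)
      if (g == "AB") {
        dc <- draw_count_depth(m, td / 2, td, band, sk)
        tumor_depth[ii] <- dc$depth
        tumor_alt[ii] <- dc$count
      } else if (g == "AA") {   # all reads carry the kept allele
        tumor_depth[ii] <- draw_depth(m, td, band, sk)
        tumor_alt[ii] <- tumor_depth[ii]
      } else {                  # "A": B lost, depth halved, count == depth
        tumor_depth[ii] <- draw_depth(m, td / 2, band, sk)
        tumor_alt[ii] <- tumor_depth[ii]
      }
    }
  }
  counts <- data.frame(
    chrom = "1", pos = seq_len(n),
    normal_ref_count = normal_depth - normal_alt,
    normal_alt_count = normal_alt, normal_depth = normal_depth,
    tumor_ref_count = tumor_depth - tumor_alt,
    tumor_alt_count = tumor_alt, tumor_depth = tumor_depth,
    stringsAsFactors = FALSE
  )
  het <- lab %in% c("A", "AB")  # heterozygous germline loci
  loci <- data.frame(
    chrom = counts$chrom, pos = counts$pos,
    logR = compute_logR(counts),
    logOR = compute_logOR(counts, het = het),
    het = het, stringsAsFactors = FALSE
  )
  out <- new_sim_dataset(loci, z, space, config)
  out$counts <- counts
  out
}

#' Probability of correct genotype identification
#'
#' The replicate-averaged 0/1 indicator that the decoded genotype equals
#' the truth, per locus, plus the same aggregated over loci sharing a true
#' genotype.
#'
#' @param decoded List (or matrix, replicates in rows) of decoded state
#'   index vectors.
#' @param truth List of matching truth vectors, or a single vector shared
#'   by all replicates.
#' @param labels Optional state labels for naming the per-genotype
#'   aggregate.
#' @return List with `per_locus` (length-N accuracy) and `per_genotype`
#'   (named accuracy by true genotype).
#' @export
probability_of_identification <- function(decoded, truth, labels = NULL) {
  if (is.matrix(decoded)) decoded <- asplit(decoded, 1)
  R <- length(decoded)
  n <- length(decoded[[1L]])
  if (!is.list(truth)) truth <- rep(list(truth), R)
  if (length(truth) != R) stop("decoded and truth replicate counts differ")
  correct <- matrix(0, R, n)
  for (r in seq_len(R)) {
    if (length(decoded[[r]]) != n || length(truth[[r]]) != n)
      stop("replicate ", r, ": locus counts differ across replicates")
    correct[r, ] <- as.numeric(decoded[[r]] == truth[[r]])
  }
  per_locus <- colMeans(correct)
  states <- sort(unique(unlist(truth)))
  per_genotype <- vapply(states, function(s) {
    num <- 0; den <- 0
    for (r in seq_len(R)) {
      at <- truth[[r]] == s
      num <- num + sum(correct[r, at])
      den <- den + sum(at)
    }
    num / den
  }, numeric(1))
  names(per_genotype) <- if (!is.null(labels)) labels[states] else states
  list(per_locus = per_locus, per_genotype = per_genotype)
}
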