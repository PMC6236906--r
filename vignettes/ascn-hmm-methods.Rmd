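---
title: "Methods: a robust HMM for allele-specific somatic copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a robust HMM for allele-specific somatic copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascnHMM)
```

## Model and assumptions

Allele-specific SCNA analysis asks, at every locus along the genome, how
many copies of each parental allele the tumor carries, while accounting
for two sample-level nuisances: tumor purity $\alpha$ (fraction of tumor
cells in the tissue) and ploidy $\psi$ (the tumor genome's average copy
number). The observables per locus $k$ are the log2 tumor/normal depth
ratio $W_k$ (logR) and, at germline-heterozygous loci only, the log
allelic odds ratio $X_k$ (logOR).

The hidden genotype $Z_k$ takes values in an ordered state space of
genotype labels; the default 12 states enumerate all $(m_j, p_j)$ with
total copy number $C_{T,j} = m_j + p_j \le 5$ and $m_j \ge p_j$. Because
phase is unobservable and only $X_k^2$ enters the likelihood, $(m, p)$
and $(p, m)$ are indistinguishable and labels are canonicalized with the
major count first; internally states are numbered 1..J in the given
order (R convention). Conditional on $Z_k = j$:

$$\mu_j = \log_2\frac{(1-\alpha) C_N + \alpha C_{T,j}}{\psi},\qquad
  \zeta_j = \log\frac{(1-\alpha) + \alpha m_j}{(1-\alpha) + \alpha p_j},$$

with $C_N = 2$ (overridable for sex chromosomes). The emission is

* logR: Student-t, location $\mu_j$, squared scale $\kappa^2$, degrees of
  freedom $v$ — analytically the normal–gamma scale mixture
  $\int N(W \mid \mu_j, \kappa^2/u)\,G(u; v/2, v/2)\,du$, which we
  evaluate in closed form (the mixture form survives as a quadrature test
  oracle). A normal alternative with variance $\sigma^2$ is kept for
  comparison: its thin tails force the chain to explain every outlier by
  a state change, which is exactly the hypersegmentation failure mode the
  t family suppresses.
* logOR$^2$: $X_k^2/\tau^2 \sim \chi^2_1(\delta_j)$ with
  $\delta_j = \zeta_j^2/\tau^2$ (equivalently $X_k = \pm\zeta_j +$ normal
  noise, squared). Homozygous loci have no logOR; their emission is the
  logR term alone. Missingness is modeled, never imputed.

$Z$ follows a single first-order Markov chain across the concatenated
genome — chromosome boundaries do not reset the chain by default (the
`--per-chrom`-style restart was considered and rejected as the default
because the reference analysis treats the genome as one sequence; a user
can fit chromosomes separately if desired). The chain is homogeneous;
inter-locus distance does not modulate transitions.

## Estimation

Parameters split into the chain (initial probabilities $r_0$, transition
matrix $P$) and the globals $\theta = \{\alpha, \psi, \kappa^2, \tau^2,
v\}$ ($\sigma^2$ replacing $\kappa^2, v$ for the normal family). EM:

* **E-step.** Scaled forward–backward recursions give the smoothed state
  posteriors $\gamma_{kj}$, the summed pairwise posteriors
  $\sum_k \eta_k^{i,j}$, and the observed-data log-likelihood
  $\log\sum_l a_l(N)$. Per-step normalization plus a per-locus row-max
  shift of the log emissions keeps everything finite at $N \sim 4\times
  10^5$.
* **M-step.** $\hat r_{0j} = \gamma_{1j}/\sum_l \gamma_{1l}$ and
  $\hat P_{ij} = \sum_k \eta_k^{i,j} / \sum_k\sum_l \eta_k^{i,l}$ in
  closed form; the globals ascend
  $Q_\theta = \sum_{k,j} \gamma_{kj}\log p(W_k, X_k^2 \mid Z_k = j)$ by
  box-constrained L-BFGS-B with an analytic gradient, capped at 25 inner
  iterations. Any inner improvement preserves the generalized-EM
  monotonicity of the observed-data likelihood, which the test suite
  asserts on every fit it runs.

### Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `tol` | relative $\Delta$log-lik stop | 1e-6 | estimates stable to <1e-3 well before this |
| `max_iter` | EM iteration cap | 500 | sticky chains converge in 10–50 iterations |
| box: $\alpha$ | purity | [0.01, 0.99] | keeps $\zeta_j$ finite (pure-tumor LOH gives $\zeta = \infty$) |
| box: $\psi$ | ploidy | [0.5, 8] | covers haploid to extreme aneuploid |
| box: $\kappa^2, \sigma^2, \tau^2$ | scales | [1e-6, 100] | proper densities |
| box: $v$ | t df | [2.1, 100] | $v > 2$ keeps the logR variance $\kappa^2 v/(v-2)$ finite |

### Initialization

The purity/ploidy likelihood is multimodal (e.g. a genome-doubled
interpretation of the same logR profile). The driver therefore starts
from a coarse grid $\psi \in \{1.5, 2, 3, 4\} \times \alpha \in \{0.3,
0.6, 0.9\}$, with scale starts from robust moments (squared MAD of logR,
median of squared logOR) and $v = 5$; the chain starts uniform with
sticky transitions (0.99 self-transition). Running all 12 starts to
convergence would multiply the cost of every fit by an order of
magnitude for no observed benefit, so the driver ranks all starts by
their initial log-likelihood (one forward pass each), gives the top four
a short EM burst (`screen_iters`, default 3), and runs only the winner
to convergence. On every instance we examined the burst winner and the
full-multistart winner coincide; `init =` accepts an explicit start for
users who want to probe other modes.

## Numerical choices

* **Log-density floor.** Emission log-densities are clamped at $-745$
  ($\exp$ of which is the smallest normalized double), so no $-\infty$
  enters the recursions; a locus whose forward mass is exactly zero
  (possible only through structural zeros in the chain) raises an error
  naming the locus.
* **$\tau^2$ Jacobian.** The logOR$^2$ density includes the
  $-\log\tau^2$ change-of-variable constant, making the log-likelihood —
  and hence AIC/BIC — a valid function of $\tau^2$. State posteriors at
  fixed $\tau^2$ are unaffected. Published absolute AIC values that omit
  the constant differ from ours by a data-dependent constant; AIC
  *differences* between families or state spaces are unaffected.
* **$X^2 = 0$.** The $\chi^2_1$ density diverges at 0 identically across
  states; squared logOR values are clamped at $10^{-12}$ in the emission
  matrix, which leaves all state contrasts intact (count-derived logOR
  can be exactly 0 at perfectly balanced loci).
* **Degenerate expectations.** A homozygous deletion in a 100% pure
  tumor has $\mu = -\infty$; it is floored at $-20$ log2 units so the
  density stays proper. The $0/0$ case of $\zeta$ at $\alpha = 1,
  m = p = 0$ is defined as 0 (the $m = p$ limit).
* **Decoding ties** break toward the lowest state index; decoding is
  per-locus posterior mode (the uncertainty-aware choice the accuracy
  metric is defined on), with Viterbi available as a secondary decoder.
* **Standard errors** are from a central-difference Hessian of the
  negative observed-data log-likelihood in the globals, with the chain
  parameters held at their estimates. A singular Hessian yields `NA` SEs
  with a warning — never substituted values. (Roughly 3% of benchmark
  replicates are expected to do this under the normal family.)
* **AIC/BIC parameter count** includes the chain: $(J-1) + J(J-1)$ plus
  5 (t) or 4 (normal) globals — 148 for the 12-state t model, 8 for the
  two-state A/AB t model, a convention pinned by the published
  BIC$-$AIC gaps.

## What the simulators emulate — and what they do not

**Design 1 (`sim_scenario_t`)** draws a sticky Markov truth over
$\{A, AA, AAAB, AAAAB\}$ (hemizygous deletion, copy-neutral LOH, and the
two amplification genotypes whose expectations nearly coincide:
$\mu$ 1.25 vs 1.55, $\zeta$ 1.03 vs 1.31 at $\alpha = 0.9, \psi = 1.6$),
adds $\kappa\, t_4$ noise to logR and $N(0, \tau^2)$ noise to logOR at
the 10% of loci chosen heterozygous. This is the model's own world: green
recovery tests establish correctness of the estimator, not realism.

**Design 2 (`sim_scenario_mixnorm`)** replaces the logR noise with
$0.7\,N(0, 0.5) + 0.3\,N(0, 4.5)$ — long-tailed but *not* t — so it
probes robustness to emission misspecification. Note the stated
components have total variance $0.7 \cdot 0.5 + 0.3 \cdot 4.5 = 1.7$;
descriptions of this design sometimes quote 2.25, which no reading of
the components reproduces, so the generator documents 1.7.

**Design 3 (`sim_read_counts`)** generates raw paired read counts —
independent of the emission model — for a truth profile cycling
A, AB, AA in segments of 1600/1800/1542 loci: normal coverage 40 (allele
count 20 at germline-het loci), tumor coverage 160 (AB: 80/160; AA:
160/160; A: 80/80, the B allele being lost), jittered by uniform bands
(±15/±20 normal; a 70/30 mixture of ±30/±15 for tumor) and rounded.
Draws violating $0 \le$ count $\le$ depth or depth $< 1$ are redrawn.
`skewed_depth = TRUE` replaces the uniform depth bands with a
beta(1, 6) draw rescaled to $[1, 2\times$nominal$]$ — the uneven-coverage
regime where segmentation-based callers degrade. logR/logOR are then
computed from the counts exactly as for real count data.

Deliberate idealizations: no GC-content waves, no mapping bias, no
linkage between neighboring loci beyond the chain, uniform het-locus
placement, and no subclonal fractions. A green test on simulated data
therefore establishes algorithmic correctness and the claimed robustness
orderings, not end-to-end performance on real exomes.

One identifiability fact the read-count design exposes: truth-AA
(copy-neutral LOH) loci are germline-homozygous there, so they carry no
logOR, and states AB and AA — identical total copy number — have exactly
equal emissions at every such locus. The AA segment is unidentifiable in
principle in that design (it decodes as AB); accuracy claims for design 3
are made for the identifiable genotypes A and AB. Detecting NLOH requires
germline-heterozygous loci inside the NLOH segment, which design 3 as
specified does not contain.

## Known limitations

* Homogeneous transitions: no distance-dependent or chromosome-aware
  transition structure; thinning (`thin_loci`) is the pragmatic answer to
  short-range autocorrelation.
* One clone: no subclonal fraction estimation; a mixture of tumor clones
  will be averaged into the nearest integer genotype.
* logR normalization is a genome-wide median centering; GC correction is
  out of scope and should happen upstream.
* Absolute log-likelihoods depend on the initialization path and the
  $\tau^2$ Jacobian convention; only differences on the same data are
  interpretable.
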