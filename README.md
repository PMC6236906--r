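# ascnHMM

Allele-specific somatic copy number alteration (SCNA) calling from paired
tumor/normal sequencing summaries, with joint estimation of tumor purity and
ploidy and built-in resistance to hypersegmentation.

## The problem

Tumor whole-exome or whole-genome data yield two per-locus summaries:

- **logR** `W_k`: the log2 tumor/normal depth ratio — informative about
  total copy number;
- **logOR** `X_k`: the log odds ratio of variant vs reference allele counts
  in tumor vs normal — informative about allelic imbalance and, unlike BAF,
  robust to reference-mapping bias. It exists only at loci that are
  heterozygous in the germline.

Both are distorted by normal-cell contamination (purity α) and aneuploidy
(ploidy ψ), and logR carries heavy-tailed technical noise that makes naive
segmentation shatter the genome into spurious micro-segments
(hypersegmentation).

## The model

Each locus carries a hidden genotype state `Z_k` from a configurable space
(default 12 states: `0, A, AA, AB, AAB, AAA, AAAB, AABB, AAAA, AAAAB,
AAABB, AAAAA`, i.e. all allele-specific genotypes with total copy number
0–5). `Z` follows a first-order Markov chain along the genome. Given
`Z_k = j` with total copy number `C_T,j` and major/minor allele counts
`(m_j, p_j)`:

    E(W_k) = mu_j   = log2[ ((1-α) C_N + α C_T,j) / ψ ],   C_N = 2
    E(X_k) = zeta_j = log[ ((1-α) + α m_j) / ((1-α) + α p_j) ]

Emissions: `W_k` is Student-t with location `mu_j`, squared scale κ² and v
degrees of freedom (the heavy tail absorbs outliers instead of forcing
state changes; a normal emission with variance σ² is available for
comparison), and `X_k²/τ²` is noncentral chi-square with 1 df and
noncentrality `zeta_j²/τ²`; homozygous loci contribute the logR term only.
All parameters — θ = {α, ψ, κ², τ², v} plus the chain's initial and
transition probabilities — are estimated by a generalized EM algorithm:
scaled forward–backward posteriors in the E-step, closed-form chain
updates and box-constrained L-BFGS-B ascent of the expected emission term
in the M-step. Standard errors come from the numeric Hessian of the
observed-data log-likelihood; AIC/BIC compare emission families and state
spaces. Decoding is per-locus posterior mode.

## Worked example

```r
library(ascnHMM)

# benchmark world: purity 0.9, ploidy 1.6, t4 logR noise (kappa2 = 0.3),
# logOR noise variance 0.5, 90% homozygous loci, sticky truth chain over
# genotypes A, AA, AAAB, AAAAB
ds  <- sim_scenario_t(sim_config("t_logR", n_loci = 2000), seed = 42)
fit <- fit_ascn_hmm(ds$loci, ds$space, family = "t")
fit
#> Allele-specific copy number HMM fit (t family, 4 states)
#>   purity 0.907  ploidy 1.621  logR scale^2 0.3034  logOR var 0.4644  df 4.03
#>   loglik -2708.82  AIC 5457.64  BIC 5569.66  (17 EM iterations, converged)

probability_of_identification(list(fit$decoded$state_index),
                              ds$truth, ds$space$label)$per_genotype
#>         A        AA      AAAB     AAAAB
#> 1.0000000 0.9928571 0.9952381 0.9297052
```

The fit recovers the generating purity/ploidy/scales (0.9 / 1.6 / 0.3 /
0.5, df 4) and decodes 93–100% of loci per genotype; the hardest contrast
is AAAB vs AAAAB, whose expected logR (1.25 vs 1.55) and logOR (1.03 vs
1.31) nearly coincide. Segment export:

```r
write_segments(fit$decoded, "profile.segments.bed")   # 0-based half-open
```

Real data enter either as a locus table (`chrom pos logR logOR het`, TSV,
`NA` logOR at homozygous loci) via `read_locus_table()`, or as paired
allele counts via `read_allele_counts()` + `compute_logR()` /
`compute_logOR()`; `thin_loci(loci, 10)` keeps every 10th locus to damp
the short-range autocorrelation the chain does not model.

## Command line

```sh
Rscript inst/cli/ascnhmm.R simulate --scenario t --n 10000 --reps 5 --seed 1 --out sims/
Rscript inst/cli/ascnhmm.R fit --input sims/rep001.tsv --family t \
    --states A,AA,AAAB,AAAAB --out fit1 --write-posteriors
Rscript inst/cli/ascnhmm.R evaluate --dir sims/ --family t --out accuracy.json
```

## Documentation

The methods vignette (`vignettes/ascn-hmm-methods.Rmd`) describes the
model, the numerical choices, what the simulators do and do not emulate,
and known limitations.
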