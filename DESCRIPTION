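Package: ascnHMM
Title: Allele-Specific Somatic Copy Number Calling with a Robust Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Maintainer", "ascnHMM", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint estimation of tumor purity, ploidy and per-locus
    allele-specific genotype from paired tumor/normal sequencing summaries
    (logR and logOR). Hidden Markov model over a genotype state space with a
    heavy-tailed Student-t emission for logR (suppressing hypersegmentation)
    and a noncentral chi-square emission for squared logOR, fitted by a
    generalized EM algorithm with scaled forward-backward recursions,
    box-constrained quasi-Newton M-steps, Hessian-based standard errors and
    AIC/BIC model comparison. Includes simulators for three benchmark
    designs with known ground truth and readers/writers for locus tables,
    allele counts and segment BED output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
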