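Package: targetmr
Title: Drug-Target Mendelian Randomization with Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization for drug-target discovery
    from GWAS and molecular QTL summary statistics. Builds cis-QTL
    instrument sets (cis-window selection, variance explained and
    F-statistics, LD clumping), harmonizes exposure and outcome effects
    (allele alignment, palindrome removal, Steiger directionality
    filtering), and fits a battery of causal-effect estimators (Wald
    ratio, multiplicative random-effects IVW, MR-Egger, weighted median,
    weighted mode, robust adjusted profile score, maximum likelihood)
    with sensitivity diagnostics (Cochran's Q, Egger intercept, Radial
    MR, MR-PRESSO, leave-one-out). Includes gene-level discovery gating
    with Bonferroni, Benjamini-Hochberg and q-value corrections,
    replication and I-squared gated meta-analysis, summary-data-based MR
    (SMR) with the HEIDI linkage test and a three-step methylation
    mediation analysis, a phenome-wide causal scan, and a synthetic
    summary-statistics generator with known causal truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), metafor, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
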