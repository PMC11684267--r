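---
title: "Drug-target Mendelian randomization with summary statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem and the model

Gout is driven by urate handling and inflammatory signalling, and most of
its heritable risk maps to regulatory variation. Drug-target Mendelian
randomization (MR) screens *druggable genes* for causal effects on disease
risk by using cis-QTL variants — variants near a gene that shift its
expression (or a CpG's methylation, or a protein's abundance) — as
instrumental variables. Under the three instrumental-variable assumptions
(relevance, independence from confounders, and no effect on the outcome
except through the exposure), the ratio of a variant's outcome effect to
its exposure effect estimates the causal effect of the exposure on the
outcome. With a standardized molecular exposure and a case-control
outcome, that effect is a log-odds change per SD of expression.

All computations are two-sample: the exposure and outcome associations come
from non-overlapping studies and only summary statistics (per-variant beta,
SE, allele pair, frequency, p, N) are touched.

## Instrument construction

For a gene annotated on `[start, end]`, candidate instruments are cis
variants inside `[start - w, end + w]` with `w = 100` kb (1-based,
inclusive on both ends). A per-gene BH FDR filter (default 0.05) mimics the
significance filtering of public cis-eQTL resources. Instrument strength is
summarized per variant by the proportion of variance explained,

$$\mathrm{PVE} = \frac{\beta^2}{\beta^2 + N\,\mathrm{se}^2},$$

and the corresponding F-statistic

$$F = \frac{N - k - 1}{k}\cdot\frac{\mathrm{PVE}}{1 - \mathrm{PVE}},$$

with `k = 1` because strength is assessed one variant at a time. Variants
with `F < 10` are excluded; the inequality is strict, so `F = 10` is
retained. Greedy LD clumping (retain the smallest p, drop everything with
`r^2 >= 0.1` within a 10,000 kb window, repeat) leaves an approximately
independent instrument set; p-value ties break by ascending position then
lexicographic id, so the result is invariant to input row order. The
10,000 kb window is effectively region-wide for cis windows; it is
implemented literally for generality.

## Harmonization

Exposure and outcome records are aligned to the exposure's effect allele:
matching allele pairs are kept, swapped pairs flip the outcome beta and
frequency, anything else is dropped as incompatible. Palindromic variants
(A/T, C/G) cannot be strand-resolved from alleles alone; they are dropped
when the minor-allele frequency exceeds 0.42 (strict) in *either* dataset
— the threshold is applied to both sides because an ambiguous frequency in
either study defeats the resolution; a missing frequency on a palindromic
variant drops it conservatively. Steiger filtering removes variants whose
outcome-side PVE exceeds their exposure-side PVE (wrong causal direction);
it is implemented as the deterministic PVE comparison, reusing the same
PVE formula, rather than a z-test on transformed correlations — the filter
is a directionality rule, and the deterministic form makes it reproducible
and assumption-light. Every drop carries a reason code; nothing is raised.

## The estimator battery

`mr_fit()` is the central fitting function and returns a classed object
with `print`, `summary`, `coef`, `confint`, `residuals` and `plot`
methods. Routing follows standard practice: one instrument gives the Wald
ratio `beta_out / beta_exp` with first-order delta-method SE
`se_out / |beta_exp|`; two or more give inverse-variance weighted (IVW)
weighted least squares through the origin with weights `1/se_out^2` under
a *multiplicative random-effects* model — the fixed-effect SE is scaled by
`max(1, sqrt(Q/(k-1)))`, so overdispersion widens intervals but
underdispersion is never rewarded.

Five auxiliary estimators rest on different identifying assumptions:

* **MR-Egger**: weighted regression with an intercept after orienting
  exposure effects positive; the intercept estimates directional
  pleiotropy and its t-test (k − 2 df) is the pleiotropy diagnostic; the
  residual SD is floored at 1, mirroring the IVW convention.
* **Weighted median**: interpolated weighted median of per-variant ratios,
  weights `beta_exp^2/se_out^2`; SE by parametric bootstrap (default
  1,000 replicates, seeded).
* **Weighted mode**: mode of the kernel-smoothed weighted ratio density;
  bandwidth `0.9 k^{-1/5}` times the weighted SD of ratios
  (Silverman-type); ties at the density maximum break toward the candidate
  with larger local weight mass, then smaller absolute value; bootstrap SE.
* **RAPS**: root of the profile score
  `sum_j psi(t_j) dt_j/dbeta = 0` with
  `t_j = (b_y - beta b_x)/sqrt(se_y^2 + beta^2 se_x^2)`, which accounts
  for exposure-side measurement error; `psi` is Huber (c = 1.345) by
  default or the identity. The SE uses the model-based information
  (expected `psi` moments under the normal), which is stable at the small
  instrument counts typical of cis regions, where the empirical sandwich
  is noisy.
* **Maximum likelihood**: profile likelihood in the causal effect after
  profiling out the true exposure effects; SE from observed information.
  As exposure uncertainty vanishes, RAPS (identity score) and ML both
  reduce to fixed-effect IVW — a limit the tests verify numerically.

Direction agreement of all five auxiliary estimates with IVW is the
robustness criterion; an estimate of exactly zero has no direction and
counts as inconsistent (boundary-safe). Missing estimators (too few
instruments) fail the check under the strict default.

Sensitivity diagnostics: Cochran's Q with its chi-square p; the Egger
intercept test; leave-one-out IVW (flagging omissions that flip the sign
or leave the full-data CI); Radial MR with modified second-order weights
iterated to convergence, flagging variants whose Q contribution exceeds
the `chi^2_1` 0.95 quantile (no Bonferroni by default, matching common
Radial-MR usage; both knobs are arguments); and MR-PRESSO, whose global
test compares the observed leave-one-out residual sum of squares with a
parametric null simulation and whose per-variant outlier p-values are
Bonferroni-corrected. The MR-PRESSO distortion test is not implemented.

## Discovery gating, replication, meta-analysis

Discovery IVW p-values across all genes pass through three multiplicity
gates — Bonferroni, BH, and q-values — all required below 0.05 (a
configurable `any`-gate relaxation exists). The q-value multiplies BH by
an estimate of the null proportion `pi0` from the lambda-grid
`0.05, ..., 0.95` smoothed with a cubic spline and read off at the largest
lambda, clamped to (0, 1]; with fewer than 20 genes the estimate is
unstable and `pi0 = 1` is used, making q-values coincide with BH —
conservative by construction.

Genes passing discovery are refitted in an independent replication cohort,
and the two IVW estimates are pooled by inverse variance. With two
studies, Cochran's Q has 1 df and `I^2 = max(0, (Q-1)/Q) * 100`; below 50
(strict) the fixed-effect result is reported, otherwise DerSimonian–Laird
random effects. The final call requires all three gates, direction
consistency, and meta-analysis p < 0.05. Radial-MR outliers are removed
*before* the headline discovery fit and the model is refitted — outlier
exclusion precedes estimation, with an argument to disable removal.
MR-PRESSO is available as a standalone diagnostic but is not run per gene
inside the pipeline, since outlier handling is already delegated to
Radial MR. One gene's failure (e.g. no surviving instruments) is isolated
and reported, never fatal to the run.

## SMR and HEIDI

The SMR test asks whether the strongest cis-QTL signal and the GWAS signal
at the same variant are consistent with a shared effect:
`T_SMR = z_qtl^2 z_gwas^2 / (z_qtl^2 + z_gwas^2)` on `chi^2_1`, with
effect `b_smr = b_gwas/b_qtl`. `T_SMR` is symmetric in the two z-scores
and bounded by the weaker leg, so the test is never more significant than
its weaker association.

HEIDI separates a single shared causal variant (pleiotropy) from distinct
variants in LD (linkage). Eligible variants have QTL p below 1.57e-3
(`z^2 > 10`), excluding the top variant, capped at the 20 strongest;
below 3 eligible variants the p is reported as not available and the HEIDI
gate fails conservatively (a pass-through option exists). For each
eligible variant, `d_i = b_smr(i) - b_smr(top)`; the covariance of `d`
follows from the LD correlations and per-variant z-scores by the delta
method. The default statistic is the sum of squared standardized `d`'s
with a Satterthwaite moment-matched scaled-chi-square tail, which behaves
well at desk-scale regions; a quadratic-form variant
(`d' V^{-1} d`, eigenvalue floor 1e-8 against near-collinear LD) is
available by argument. The calibration tests assert rejection at the 0.01
level stays within [0.002, 0.03] under a single shared causal variant,
and that linkage scenarios push the p distribution down.

The three-step mediation analysis runs SMR+HEIDI for (1) gene expression
to outcome, (2) CpG methylation to outcome, (3) CpG methylation to gene
expression. A candidate passes when all three SMR p-values are below
0.05, top variants are genome-wide significant (p < 5e-8) on both legs of
every step, and all available HEIDI p-values exceed 0.01. The mediation
sign chain — sign(step 3) x sign(step 1) against sign(step 2) — is
reported alongside, and the transcript/protein consistency check demands
both omics records be individually credible (SMR p < 0.05, HEIDI
p > 0.01) before comparing signs.

## Phenome-wide scan

A gene's instrument set is scanned across many outcome traits with the
same harmonize-then-IVW machinery; significance uses `alpha/m` where, by
default, `m` is the number of traits *requested* — failed traits still
count toward the correction, mirroring a fixed published phenome size —
with an option to use the number successfully scanned. Given the sign of
the gene's effect on the primary disease, significant trait rows are
labelled: an intervention pushing the exposure against the disease
direction moves each trait by `-sign(b_disease) * b_trait`, so trait
associations sharing the disease sign are `beneficial`, opposite signs
`adverse`. The convention is recorded in the output attributes rather than
asserted as universal.

## The synthetic generator

Everything is validated against simulations with known truth, generated
directly on the summary-statistic scale (no individual-level genotypes):

* **LD**: AR(1) within blocks (`r_ij = rho^{|i-j|}`), zero across blocks;
  deterministic and positive semi-definite by construction.
* **Exposure QTLs**: true effects at chosen causal variants, marginal
  effects `R b_true`, standard errors `1/sqrt(N_exp)` for a standardized
  exposure, sampling noise with covariance `se_i se_j r_ij`.
* **Outcome GWAS**: marginal log-odds effects
  `beta_causal * b_exposure + (R alpha)` plus noise, where `alpha` are
  per-variant direct effects — zero (`none`), mean-zero (`balanced`) or
  mean-shifted (`directional`) pleiotropy. Standard errors follow the
  case-control scale `1/sqrt(N_out * phi(1-phi))`; the default case
  fraction `phi = 0.1` is typical of biobank case-control GWAS of common
  inflammatory disease. Exposure and outcome samples are non-overlapping
  by construction.
* **Mediation regions**: methylation marginals first, expression
  `b_me x` methylation, outcome `b_eo x` expression, each with optional
  noise — so with noise off every marginal is an exact chain product,
  checkable variant by variant.
* Effect-allele frequencies are uniform on (0.05, 0.95); a configurable
  fraction of variants is forced palindromic with frequency near 0.5 to
  exercise the ambiguity filter. Default sample sizes mirror large public
  resources (31,684 exposure; 272,412 outcome).

Exposures are standardized to unit variance throughout, consistent with
effects quoted per SD of expression or methylation.

What the generator does *not* emulate: realistic allele-frequency spectra,
imputation quality, sample overlap, population stratification, winner's
curse in instrument selection from the same data, or non-normal effect
distributions. Passing tests therefore demonstrate the *statistical
machinery* is correct and calibrated under the stated model, not that any
particular real-data finding would reproduce.

## Validation problem sizes and numerical choices

The test suite validates: IVW recovery (truth 0.3 log-odds/SD, five
independent instruments, 50,000 samples per side, 500 replicates; mean
within 0.3 +/- 0.02 and 95% CI coverage in [0.93, 0.97]); type-I error
(1,000 null replicates; rejection at 0.05 within [0.03, 0.07]); SMR null
calibration over 1,000 regions; HEIDI calibration over 500 regions of 20
variants at rho = 0.85; and the end-to-end pipeline on studies of one
causal gene (0.5 log-odds/SD, 100,000 samples per cohort) among 50 nulls,
30 variants per gene, requiring the exact truth table in at least 95% of
20 seeded runs. These sizes keep each property statistically sharp while
the whole suite runs in minutes on one core.

Numerical choices worth knowing: RAPS brackets its root around the IVW
estimate and doubles the bracket until the score changes sign (error if
none); ML optimizes on a bracket around IVW and rejects boundary optima;
bootstrap SEs and all simulations take explicit seeds, and every
stochastic function restores the caller's RNG state; clumping and mode
tie-breaks are deterministic; LD matrices are validated (symmetry to
1e-8, unit diagonal, PSD to -1e-6) on construction.

## Known limitations

Only two-study meta-analysis is implemented (the two-cohort design);
multivariable MR, colocalization, binary QTL storage formats and
reference-panel LD estimation are out of scope. The q-value `pi0`
smoother needs a few dozen p-values to be informative. HEIDI's delta-method
covariance assumes reasonably strong eligible QTL signals (enforced by the
`z^2 > 10` eligibility rule); very weak regions return NA rather than a
poorly calibrated p.
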