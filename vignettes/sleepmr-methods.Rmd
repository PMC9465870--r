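---
title: "Methods: linear and nonlinear Mendelian randomization for sleep duration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear and nonlinear Mendelian randomization for sleep duration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmr)
```

## The problem

Observational associations between habitual sleep duration and pregnancy or
perinatal outcomes (stillbirth, preterm birth, gestational diabetes,
hypertensive disorders, perinatal depression, low/high birthweight,
birthweight) are confounded and plausibly nonlinear: both short and long
duration may raise risk. `sleepmr` implements the two complementary genetic
strategies for this question and the observational comparison, together with
a synthetic-cohort generator so every stage can be exercised, calibrated and
stress-tested with known ground truth.

The genetic instrument is a panel of independent biallelic SNPs associated
with self-reported sleep duration, combined into an *unweighted* genetic
risk score (GRS): the per-person count of duration-increasing alleles. The
panel emulated by the generator has 78 SNPs jointly explaining about 0.69%
of exposure variance, which at one-sample scale (n ≈ 175,000) corresponds to
an instrument F-statistic near 1200 via F = R²(n−2)/(1−R²). Self-reported
duration comes in integer hours; values below 2 h or above 12 h are treated
as non-response by `exposure_qc()` (the boundaries themselves are kept).

## Linear two-sample MR

Per-SNP summary statistics (`estimate_snp_trait()`) feed, after allele
harmonization (`harmonize()`), the standard estimator family:

* **Wald ratio** for one variant: β = β_zy / β_zx, with first-order delta SE
  `se_zy/|β_zx|` by default (a second-order option adds the
  instrument-uncertainty term).
* **IVW** (`mr_ivw()`): the zero-intercept weighted regression of SNP-outcome
  on SNP-exposure associations with weights 1/se_zy², identical to the
  inverse-variance-weighted mean of Wald ratios with weights β_zx²/se_zy².
  Between-SNP heterogeneity is Cochran's Q on k−1 df. The default
  *multiplicative random-effects* model scales the SE by
  `sqrt(max(1, Q/(k−1)))`; several perinatal outcomes show real between-SNP
  heterogeneity, and this default never narrows the CI. A fixed-effect flag
  is provided, and reports label which was used.
* **MR-Egger** (`mr_egger()`): the same regression with a free intercept
  estimating average directional pleiotropy. Instrument-exposure
  associations are pre-oriented non-negative — without this the intercept is
  meaningless and results would depend on arbitrary allele labelling.
* **Weighted median** (`mr_weighted_median()`): ordered Wald ratios
  interpolated at standardized midpoint cumulative weight 0.5; consistent
  while valid instruments carry ≥50% of weight. Its SE is a parametric
  bootstrap (default `n_boot = 1000`, seed mandatory).
* **Leave-one-out** (`mr_leave_one_out()`) and instrument-subset reruns
  (`snp_subset()`, membership supplied as configuration).

Because the exposure GWAS and the individual-level cohort overlap in
practice, the one-sample data are split in half (`split_crossover()`;
odd n places the extra row in half B), summary statistics are computed in
each half, MR crosses exposure-A with outcome-B and vice versa, and the two
crossed estimates are pooled by fixed-effects inverse-variance meta-analysis
(`meta_fixed()`, which also serves cross-cohort pooling with between-study
Q). Inference is normal-theory throughout: all inputs are large-sample
summary statistics.

## Nonlinear MR by residual stratification

Stratifying directly on the exposure would condition on a collider (the
exposure is a descendant of both score and confounders) and bias
within-stratum IV estimates. Instead `residual_exposure()` removes the
mean-centred genetic contribution (observed duration minus
`grs·β̂ − mean(grs·β̂)`, keeping the observed mean and units),
`stratify_residual()` cuts the residual into near-equal quantile groups
(three or five in practice; fixed boundaries accepted as configuration), and
`stratum_wald()` computes within each stratum the ratio of the outcome-GRS
slope (logistic for binary outcomes, linear for birthweight) to the
exposure-GRS slope, i.e. a per-stratum Wald ratio per 1 h/day. Differences
across strata are tested by Cochran's Q
(`heterogeneity_across_strata()`) and by weighted meta-regression of the
stratum estimates on the stratum mean of *observed* duration
(`nonlinearity_metareg()`): under a quadratic effect the local slope is
linear in exposure, so the meta-regression slope estimates twice the
curvature. `iv_constancy()` applies the same two tests to the per-stratum
exposure-GRS slopes, probing the method's constancy assumption. Finally
`classify_pattern()` maps the ordered stratum CIs plus the overall linear
estimate onto dose-response labels (U-shaped, reverse-J, J, linear, null,
inconclusive) through an editable JSON rule table
(`inst/extdata/pattern_rules.json`) — the rules are data, not code, because
reasonable labelling conventions differ.

### Integer-reported exposure: a real and documented limitation

The genetic contribution to sleep duration has a standard deviation near
0.09 h — two orders of magnitude finer than the 1-hour reporting grid. The
residual therefore clusters at integers, and quantile cuts can fall *inside*
a reporting level, where ordering by the residual is ordering by the genetic
score itself. Three measurable consequences (all reproduced by this
package's simulations):

* a stratum lying wholly inside one reporting level has essentially no
  exposure variation; its Wald ratio is returned with an enormous SE and is
  effectively ignored by the inverse-variance-weighted tests (degraded, not
  fatal);
* within-stratum score-exposure slopes are selection-inflated, which shrinks
  per-stratum SEs while leaving the ratio estimates approximately consistent
  — within-group instrument F can then exceed what the raw R² implies;
* under strong confounding the coarsening lets the score correlate with the
  confounder inside strata, a leak that is absent when the exposure is
  continuous.

Accordingly the test suite checks calibration through the full
integer-reporting pipeline (valid under the null), checks parameter recovery
with tertiles (every stratum then spans several reporting levels), and
demonstrates the collider-bias contrast — raw stratification biased,
residual stratification unbiased — on the continuous exposure, the regime
the residual method assumes. Doubly-ranked stratification, the published
remedy for coarsened exposures, is deliberately out of scope.

## Observational comparison (multivariable regression)

Reported duration is collapsed to the categories ≤5, 6–7, 8–9 and ≥10 h/day
(`categorize_exposure()`). `fit_categorical_model()` fits indicator coding
against the 8–9 h reference; `fit_midpoint_model()` recodes the categories
to their midpoints 3.5, 6.5, 8.5 and 11 h/day and fits a single linear term.
Both use the same rows, confounders and family, so the midpoint model is
nested and `lrt_nonlinearity()` compares them: statistic
2(LL_cat − LL_mid) ≥ 0 on (categories − 1) − 1 = 2 df. Multiple-imputation
workflows are supported at the pooling stage: `rubins_rules()` combines
per-imputation estimates with T = W + (1 + 1/m)B and the standard
small-sample df; the imputation engine itself is external by design (the
package consumes any per-imputation results), and `complete_records()`
implements the complete-case sensitivity path. A single standard-Gaussian
composite stands in for the seven-confounder block: the adjustment is
exercised structurally, not per covariate.

## The synthetic-cohort generator

`simulate_cohort()` draws, under one mandatory seed:

* genotypes: Hardy–Weinberg dosages, independent SNPs (no LD by design);
* optional fetal genotypes: one maternally transmitted allele plus one
  population allele, giving the 0.5 maternal-fetal dosage correlation that
  `adjust_for_fetal()` exploits;
* exposure: baseline (default 7.2 h, the typical mean of QC'd self-report) +
  mean-centred genetic component + confounder effect (default 0.3 h per unit
  of a standard-Gaussian composite) + Gaussian noise (default 1.05 h, giving
  a total SD near 1.1 h). Per-SNP effects default to equal magnitude and
  random sign — only the aggregate variance explained is anchored — and are
  rescaled so the realized genetic variance fraction equals `target_r2`
  (default 0.0069). Reported hours are rounded to the nearest integer and
  clipped to [1, 23]; implausible values are removed only by `exposure_qc()`,
  mirroring the analysis-side QC;
* outcomes: binary outcomes are Bernoulli with logit = intercept +
  f_shape(exposure) + confounder term, the intercept solved by bisection
  (tolerance 1e-4 on the prevalence scale) so the marginal prevalence matches
  the request — prevalence is configuration because it varies widely across
  real cohorts (0.4% to 28%); birthweight is Gaussian (default mean 3600 g,
  SD 500 g). Every shape (`effect_shape()`: null, linear, quadratic,
  piecewise) evaluates to 0 at its reference exposure, so risk shifts are
  relative to the reference;
* missingness: MCAR, or MAR logistic in a fully observed driver with the
  intercept solved for the marginal rate.

What the generator does *not* emulate: linkage disequilibrium, genotyping
error, population stratification, selection into the cohort, non-Gaussian
exposure noise, correlated multi-outcome structure, or realistic confounder
sets. Passing tests therefore demonstrate correctness of the estimators and
the stated statistical properties under the assumed data-generating
structure — not robustness to everything real cohorts can do.

## Numerical choices

* Weighted least squares with known variances uses (XᵀWX)⁻¹ covariance
  (fixed-effect meta convention), not residual-variance scaling.
* Per-SNP regressions use a vectorised Frisch–Waugh OLS path and, for
  logistic models without covariates, an exact Newton solver on the
  per-dosage-class sufficient statistics (integer dosages have only three
  classes); both are verified against `lm()`/`glm()` in the test suite.
  Separated logistic fits are flagged with a missing SE rather than trusted.
* Quantile stratification cuts stable ranks (ties broken by position), so
  group sizes differ by at most the tie count at boundaries; fixed-boundary
  schemes use half-open intervals [lo, hi).
* Strata with no cases, no controls, or no usable exposure variation yield
  missing or huge-SE estimates with a warning and are dropped or effectively
  ignored downstream — rare outcomes must not crash the pipeline.
* The bisection for outcome intercepts brackets on [−40, 40] and stops at
  1e-4 prevalence tolerance.
* All pipeline randomness derives from one seed via deterministic per-stage
  child seeds; identical config + seed reproduces byte-identical reports.

## Problem sizes used by the automated checks

The test suite works at deliberately chosen scales: estimator oracles run on
constructed instances in milliseconds; null calibration uses 1000 replicates
of n = 20,000; parameter recovery 250 replicates of n = 100,000; nonlinearity
detection 100 replicates of n = 100,000; the collider-bias contrast 500
replicates of n = 20,000. These sizes keep Monte-Carlo error well inside the
asserted tolerance bands while remaining practical on a single CPU.

## Known limitations

* The residual-stratification coarsening issue above; with integer-reported
  exposure prefer few, wide strata or externally chosen boundaries spanning
  several reporting levels.
* At the emulated instrument strength, a single binary-outcome stratum's
  Wald ratio is intrinsically noisy (per-replicate SE comparable to
  plausible effect sizes); per-stratum conclusions about rare outcomes need
  either pooling or far larger cohorts.
* Weak-instrument attenuation in two-sample designs is approximately
  K/(nR² + K) toward the null; with 78 SNPs at R² = 0.69% this is ~10% at
  n = 100,000 per association sample and shrinks only with larger n. The
  split cross-over design trades this (conservative) bias for protection
  against winner's-curse and overlap bias.
* No LD clumping, proxy lookup, Steiger filtering, MR-PRESSO, mode-based or
  multivariable MR, fractional-polynomial or doubly-ranked nonlinear MR;
  survival outcomes and survey weights are out of scope.
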