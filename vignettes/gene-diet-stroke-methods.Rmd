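---
title: "Methods: polygenic risk, fruit intake, and incident stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk, fruit intake, and incident stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prsfruit)
```

This vignette documents the statistical methods implemented in
`prsfruit`, the design of the synthetic-cohort generator used to validate
them, and the numerical and design choices that a reader reproducing the
analyses should know about.  Code chunks are shown but not evaluated at
build time; every number quoted here is recomputed by the test suite or
by `scripts/acceptance.R`.

## 1. Study design being emulated

The package analyses a prospective cohort assembled from several
sub-cohorts, with genotyped participants followed from a baseline
examination to first-ever stroke, death, loss to follow-up, or an
administrative censoring date.  The exposure pair of interest is

* **genetic risk**: a weighted polygenic risk score (PRS) over a panel of
  stroke-associated SNPs, categorized by cohort quintiles into low
  (quintile 1), intermediate (quintiles 2–4), and high (quintile 5);
* **fruit intake**: habitual fresh-fruit consumption in three categories,
  `< 200 g/week`, `200 g/week to 100 g/day`, and `> 100 g/day`.

The headline questions are (i) the independent associations of each
exposure with incident stroke, (ii) whether they interact on the
multiplicative and additive scales, and (iii) what the joint exposure
implies in absolute terms — 10-year standardized cumulative incidence and
gained stroke-free years between ages 35 and 85.

## 2. Synthetic-cohort generator

Because individual-level cohort data cannot ship with a package, all
validation rests on a generator (`generator_config()`,
`generate_cohort()`) that simulates cohorts from *known* ground truth, so
that estimators can be tested by parameter recovery.

**Genotypes.** Each SNP has an allele frequency drawn uniformly on
(0.05, 0.95) and per-allele weight drawn from the magnitudes typical of
GWAS log odds ratios.  Genotypes are independent binomial(2, p) draws —
Hardy–Weinberg equilibrium with no linkage disequilibrium.  That
independence is a deliberate simplification: the score methods only
require additivity over loci, and LD would change nothing about the
estimators being validated, only the effective number of independent
variants.

**Baseline covariates.** Age, sex, education, smoking, alcohol, BMI,
blood pressure, glucose, lipids, physical activity and the remaining
diet-score components are drawn from simple parametric families with
plausible marginal moments.  Fruit intake is a two-part mixture (a
point mass of low consumers plus a log-normal continuum) so that all
three intake categories are well populated.

**Event times.** Stroke times follow a Weibull proportional-hazards
model: the cumulative hazard is `scale * t^shape * exp(lp)` where the
linear predictor `lp` carries the planted truths.  Two effect modes are
supported:

* `"category"` — log hazard ratios attach to the *true* genetic and
  fruit categories (with optional stratum-specific fruit effects via
  `true_hr_fruit_by_group`, and an optional product term
  `true_log_interaction` on the (high genetic, low fruit) corner);
* `"continuous"` — a log-linear effect of the standardized score, which
  keeps the truth exactly linear for spline-calibration studies.

Competing death is an independent exponential time; administrative
censoring is drawn uniformly over a configurable window.  Event subtypes
(ischemic, hemorrhagic, both, undetermined) are a multinomial draw among
events.  Inverting the Weibull cumulative hazard is exact, and the test
suite verifies that `scale * T^shape` is a unit exponential when all
effects are null.

**Calibration.** `calibrate_baseline_scale()` adjusts the baseline scale
by bisection on seeded replicate cohorts until the crude incidence
matches a target (default 7.7 events per 1000 person-years), erroring —
not clamping — when the target is unreachable.

**Exclusion fixtures.** The generator can plant exact numbers of records
with missing fruit data, prevalent stroke/cancer, and missing follow-up,
so the exclusion cascade can be audited against known counts.  Oracle
columns (`prs_true`, `true_*`) are kept in memory for truth checks but
stripped by `export_cohort()`.

## 3. Score construction and cohort preparation

`compute_prs()` is the weighted dot product of risk-allele counts and
panel weights, standardized against the analytic sample, with quintile
cuts `20/60/20` computed by `stats::quantile` type 7.  Ties at a cut
point fall into the lower-or-equal side, which the tests pin down with an
adversarial tie fixture.  The grouping is invariant to monotone
transformations of the weights' scale (scaling all weights rescales the
score but not the quintile membership).

`apply_exclusions()` applies, in order: missing fruit data; prevalent
stroke or cancer at baseline; missing or non-positive follow-up.  The
order matters for the per-step audit counts (a record failing several
criteria is counted at the *first* step it fails); the audit preserves
`n_input = n_excluded + n_analytic` by construction.

Derived variables: the three fruit categories use boundaries at
`200/7 g/day` and `100 g/day`, with the `100 g/day` boundary assigned to
the *middle* category (i.e. the top category is strictly `> 100 g/day`);
the healthy-diet score awards one point each for red meat `< 75 g/day`
(strict), legumes `>= 125 g/day`, fish `>= 200 g/week` and tea
`>= 3 times/week`, so `derive_diet_score(50, 150, 250, 5)` — all four
components at their ideal level — evaluates to 4; ideal physical
activity is
`>= 150 min/week` of moderate-or-vigorous activity; hypertension,
diabetes and dyslipidemia combine measured values with self-reported
diagnosis and medication.

## 4. Survival core

All hazard-ratio models are Cox proportional-hazards fits **stratified by
sub-cohort** (separate baseline hazards, shared coefficients), fitted by
`survival::coxph` with **Breslow** tie handling, wrapped by
`fit_stratified_cox()`.  Two adjustment tiers are prespecified:

* `base`: age, sex, and (for diet exposures) total energy proxies;
* `full`: base plus education, smoking, alcohol, BMI, physical activity,
  the remaining diet-score components, hypertension, diabetes,
  dyslipidemia, and family history.

Design details worth noting:

* **Constant covariates.**  A covariate with no variation carries zero
  information; rather than letting the fit fail, the wrapper strips it,
  fits the rest, and reports it back with coefficient 0 and zero
  variance rows.  A useful corollary: fitting *only* a constant yields
  the null model, whose Breslow baseline cumulative hazard equals the
  Nelson–Aalen estimator exactly — one of the closed-form oracles in the
  tests.
* **Oracles.**  The Newton–Raphson estimate is cross-checked against a
  brute-force grid search of the definition-based Breslow partial
  likelihood to `1e-4`.
* **Confidence intervals** are Wald intervals on the log scale
  throughout; **trend tests** refit with the ordinal exposure entered as
  scores 1, 2, 3.
* **Diagnostics.**  Proportional hazards via `survival::cox.zph`
  (Schoenfeld residuals); dose–response via restricted cubic splines
  (natural cubic basis, knots at prespecified quantiles) with a Wald
  test of the nonlinear terms.  The spline basis is authored in-package
  (`rcs_basis()`) and tested for value/derivative continuity at the
  knots and linear tails.

## 5. Interaction analyses

`joint_hr_grid()` fits a single fully adjusted model with a 9-level
genetic × fruit factor (reference: low genetic risk, high fruit intake)
and reports the 3×3 grid of hazard ratios with event and person-year
bookkeeping per cell.

Additive interaction uses the dichotomized corners (high vs low genetic
risk, low vs high fruit intake; the intermediate categories are dropped
and the drop is reported):

* `RERI = HR11 − HR10 − HR01 + 1` and `AP = RERI / HR11`, both of which
  the tests verify as *identities* of the fitted grid to `1e-12`;
* inference by the multivariate delta method on the log-HR scale **and**
  by a stratified nonparametric bootstrap (resampling within
  sub-cohorts, percentile intervals; replicates are seeded by a
  stream-splitting scheme so results are reproducible and independent of
  evaluation order, and more than 5% failed replicates is an error, not
  a silent omission).

Multiplicative interaction is the likelihood-ratio test of the product
terms.  The per-SNP scan repeats the additive analysis for each variant
(genotype dichotomized at carriage) with Bonferroni control at
`0.05 / n_SNPs`.  One caveat the null-calibration tests document: the
delta-method Wald test for RERI is heavy-tailed for SNPs with extreme
allele frequencies (a nearly empty genotype cell), so occasional extreme
null p-values are expected even though the overall size is near nominal;
the scan is a screen, and flagged SNPs should be confirmed by bootstrap.

## 6. Absolute risk and stroke-free years

`standardized_cum_incidence()` converts the joint Cox fit into
10-year cumulative incidence per exposure cell.  Two standardization
modes are provided:

* `"at_means"`: risk at covariate means — the pipeline default, matching
  the common reporting convention for this kind of analysis;
* `"marginal"` (g-computation): average the individual predicted risks
  over the full analytic covariate distribution, per stratum — the
  better-defined population estimand, and the one we recommend when not
  constrained by comparability.  The two coincide exactly in a model
  with no adjustment covariates and a single stratum, which the tests
  exploit as an oracle.

Both are validated against exponential closed forms and against
`survival::survfit` predictions.  Absolute risk reduction (`arr_and_trend()`)
is the low-minus-high fruit incidence difference within each genetic
stratum, with a weighted-least-squares trend across strata (scores
1, 2, 3; weights inverse bootstrap variances).

`gained_stroke_free_years()` switches to the **age timescale**: entry is
left-truncated at baseline age, and standardized survival curves are
built from age 35 to a horizon of age 85 (the package's choice of
horizon; curves are never extrapolated past the last observed age, which
is an error instead).  Gained years are the trapezoid-rule area between
the high- and low-fruit standardized curves — a restricted-mean survival
time difference — with percentile bootstrap intervals.  The closed-form
oracle: exponential curves with hazards 0.01 vs 0.02 over 50 years give
`(1 − e^{−0.5})/0.01 − (1 − e^{−1})/0.02 = 7.741` years.
`sensitivity_suite()` re-fits the headline fruit hazard ratios under
prespecified variants: the age timescale with left truncation,
continuous lifestyle covariates in place of the binary flags, and Efron
tie handling.  A competing-risk (Fine–Gray) refit is reported as not
implemented; the generator already emits competing deaths, so it can be
added without generator changes.

## 7. Pipeline and reproducibility

`run_pipeline(run_config(...))` chains generation (or ingestion of an
exported cohort directory), preparation, and inference, writing CSV/JSON
artifacts plus a manifest of MD5 hashes; identical configurations
produce byte-identical artifacts.  All randomness in the package flows
from explicit seeds; nested analyses derive child seeds by
stream-splitting from the caller's seed.

Configs round-trip through YAML and JSON at 17 significant digits so
that `config_hash()` is stable across serialization.

## 8. Problem sizes and other deliberate choices

The following are the package's own choices, made to keep the validation
suite within a modest compute budget; all are configurable.

* **Recovery simulations** use cohorts of 35,000 participants with a
  120-SNP panel, 20 seeds per target.  Recovery of the planted hazard
  ratios does not depend on the panel size (only the score's quintiles
  enter the model), so the panel is scaled down from the hundreds of
  variants a real score would use.
* **Null calibration** of the diagnostic tests uses 200 seeds at
  n = 2,000 with a 40-SNP panel, which bounds the 5%-level rejection
  rates within roughly ±3 binomial standard deviations of nominal.
* **Recovery batches are correctly specified by construction.**  Hazard
  ratios are non-collapsible: a fruit-only Cox model fitted to data
  whose hazard also varies with genetic group is attenuated relative to
  the conditional truth even though the two exposures are independent.
  Each recovery batch therefore plants only the truth its fitted model
  carries (the genetic batch has null fruit effects and vice versa; the
  joint and stratum batches fit the fully interacted model that matches
  their generating mechanism).
* **Bootstrap sizes** default to 1,000 replicates in the pipeline and
  are reduced (100–200) in examples and tests.
* The `100 g/day` fruit boundary goes to the middle category; the
  restricted-mean horizon is age 85; WLS trend scores are 1, 2, 3;
  `200 g/week` is converted as `200/7 g/day`.  Each choice is pinned by
  a unit test so that any future change is visible.
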