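# prsfruit

Gene–diet survival analysis for stroke: polygenic risk scores, fruit
intake, and their joint effect on incident stroke in prospective cohorts,
with a fully seeded synthetic-cohort generator for validation.

## The science

Large prospective cohorts have shown that both inherited susceptibility
(summarized by a polygenic risk score, PRS) and habitual fruit intake are
associated with first-ever stroke, and that the two can be studied
jointly: does a healthy diet offset a high genetic risk?  Answering that
requires a chain of survival-analysis machinery:

* a **weighted PRS** built from risk-allele counts over a panel of
  hundreds of SNPs, cut into low (bottom quintile), intermediate and high
  (top quintile) genetic risk groups;
* an audited **exclusion cascade** and derived analytic variables (fruit
  intake categories with boundaries < 200 g/week, 200 g/week–100 g/day,
  > 100 g/day; a 4-component healthy diet score; ideal physical activity;
  hypertension / diabetes / dyslipidemia flags);
* **cohort-stratified Cox proportional-hazards models** (Breslow ties,
  per-sub-cohort baseline hazards) in two adjustment tiers, with trend
  tests, restricted-cubic-spline dose–response curves and Schoenfeld
  proportional-hazards diagnostics;
* **joint 3×3 hazard-ratio grids** over genetic risk × fruit group,
  multiplicative interaction, and **additive interaction** — RERI
  (relative excess risk due to interaction, HR11 − HR10 − HR01 + 1) and
  the attributable proportion AP = RERI/HR11 — with delta-method and
  bootstrap intervals, plus a per-SNP interaction scan with Bonferroni
  control;
* **covariate-standardized 10-year cumulative incidence** from the joint
  Cox fit, absolute risk reductions (ARR) for high vs low fruit intake
  within each genetic stratum, and a weighted-least-squares trend in the
  ARRs;
* **gained stroke-free years**: differences in restricted mean event-free
  time between standardized survival curves on the age timescale
  (left-truncated entry at baseline age), from age 35 to 85.

The package implements every step, and pairs it with a generator that
simulates cohorts from known ground truth (Hardy–Weinberg genotypes, a
two-part fruit-intake mixture, Weibull proportional-hazards event times
with competing death and administrative censoring), so every estimator can
be validated by parameter recovery.

## Worked example

A small end-to-end run (sizes reduced from the defaults of 35,000
participants × 534 SNPs so it finishes in seconds):

```r
library(prsfruit)

cfg <- generator_config(n_participants = 8000, n_snps = 60, seed = 42,
                        effect_mode = "category",
                        true_hr_genetic = c(1.19, 1.51),
                        true_hr_fruit = c(0.81, 0.69))
sim <- generate_cohort(cfg)
cohort <- apply_exclusions(sim$cohort)$cohort
cohort$genetic_group <- compute_prs(sim$genotypes, sim$panel)$genetic_group

hazard_ratios(fit_stratified_cox(cohort,
                                 cox_model_spec("genetic_group", "base",
                                                "genetic")),
              terms = "genetic_group")
#>                        term       hr     lower    upper           p
#> 1 genetic_groupintermediate 1.086223 0.9029517 1.306693 0.380372144
#> 2         genetic_grouphigh 1.427368 1.1542100 1.765171 0.001026113

hazard_ratios(fit_stratified_cox(cohort, cox_model_spec("fruit_group",
                                                        "full")),
              terms = "fruit_group")
#>              term        hr     lower     upper            p
#> 1  fruit_groupmid 0.7671327 0.6560328 0.8970474 0.0008967361
#> 2 fruit_grouphigh 0.7252075 0.6016366 0.8741587 0.0007487459

reri_ap(cohort, n_bootstrap = 200, seed = 1)
#> Additive interaction (high_vs_low genetic coding)
#>   HR10 1.323, HR01 1.141, HR11 1.888
#>   RERI 0.424 (delta -0.181 to 1.029) (bootstrap -0.261 to 1.008)
#>   AP 0.224 (delta -0.074 to 0.523)

arr <- arr_and_trend(cohort, n_bootstrap = 200, seed = 1)
arr$arr$arr          # ARR (low- minus high-fruit 10-year risk) by stratum
#> [1] 0.02311824 0.02863306 0.01974791
arr$p_trend
#> [1] 0.9291562

gained_stroke_free_years(cohort, n_bootstrap = 100, seed = 1)
#> Gained stroke-free years (high vs low fruit, overall population,
#> ages 35-85): 2.03 (95% CI 0.81 to 3.22, 100 bootstrap replicates)
```

The whole analysis can equally be driven through one call:

```r
res <- run_pipeline(run_config(generator = cfg, output_dir = "results",
                               n_bootstrap_reri = 200,
                               n_bootstrap_arr = 200))
res$interaction$grid       # 3x3 joint hazard-ratio grid
res$manifest               # hashed artifact manifest
```

At the full default scale (35,000 participants, 534 SNPs, baseline scale
calibrated to a crude incidence of 7.7 per 1000 person-years) the same
code recovers the planted truths tightly; see the acceptance script
below.

## Package layout

| Area | Files |
| --- | --- |
| Generator config, SNP panel, genotypes | `R/generator_config.R`, `R/snp_panel.R` |
| Cohort simulation and calibration | `R/generate_cohort.R` |
| Polygenic score and risk groups | `R/prs.R` |
| Derived variables, exclusions, descriptives | `R/cohort_prep.R` |
| Stratified Cox core, diagnostics, rates | `R/cox.R`, `R/rcs.R` |
| Joint grids, RERI/AP, SNP scan, bootstrap | `R/interaction.R` |
| Standardized risk, ARR trend | `R/absolute_risk.R` |
| Stroke-free years (age timescale) | `R/stroke_free_years.R` |
| Pipeline, serialization, sensitivity | `R/pipeline.R` |
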