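test_that("genotypes follow Hardy-Weinberg frequencies", {
  cfg <- quick_config(seed = 11L, n = 5000L, n_snps = 30L)
  panel <- generate_snp_panel(cfg)
  g <- generate_genotypes(cfg, panel)
  expect_identical(dim(g), c(5000L, 30L))
  expect_true(all(g %in% 0:2))
  p <- panel$allele_freq
  # allele-count mean is 2p with binomial SE sqrt(2p(1-p)/n)
  se_mean <- sqrt(2 * p * (1 - p) / nrow(g))
  expect_true(all(abs(colMeans(g) - 2 * p) < 4 * se_mean))
  # heterozygote share is 2p(1-p) under HWE
  het <- colMeans(g == 1L)
  se_het <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / nrow(g))
  expect_true(all(abs(het - 2 * p * (1 - p)) < 4 * se_het))
})

test_that("a near-zero allele frequency gives an all-reference SNP", {
  cfg <- quick_config(seed = 2L, n = 1000L, n_snps = 1L)
  panel <- snp_panel("rs0000001", "A", 1e-9, 0.1)
  g <- generate_genotypes(cfg, panel)
  expect_true(all(g == 0L))
  pan_hi <- snp_panel("rs0000001", "A", 1 - 1e-9, 0.1)
  expect_true(all(generate_genotypes(cfg, pan_hi) == 2L))
})

test_that("panel constructor rejects invalid input", {
  expect_error(snp_panel(c("a", "a"), c("A", "C"), c(0.2, 0.3), c(1, 2)),
               "duplicate")
  expect_error(snp_panel("a", "A", 0, 1), "strictly inside")
  expect_error(snp_panel("a", "A", 1, 1), "strictly inside")
  expect_error(snp_panel("a", "A", 0.5, NaN), "non-finite")
})

test_that("the seed fully determines the generated cohort", {
  cfg <- quick_config(seed = 7L, n = 800L, n_snps = 12L,
                      missing_fruit_n = 5L, prevalent_n = 3L,
                      missing_followup_n = 2L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$panel, b$panel)
  other <- generate_cohort(quick_config(seed = 8L, n = 800L, n_snps = 12L))
  expect_false(identical(a$cohort$followup_years,
                         other$cohort$followup_years))
})

test_that("shape-1 latent event times are exponential", {
  # with no censoring/death/covariate effects, scale * T^shape ~ Exp(1)
  cfg <- quick_config(
    seed = 3L, n = 8000L, n_snps = 10L, effect_mode = "category",
    true_hr_genetic = c(1, 1), true_hr_fruit = c(1, 1),
    covariate_loghr = c(age = 0, male = 0),
    subcohort_scale_mult = c(1, 1, 1), death_rate = 0,
    admin_censor_years = c(1e6, 1e6 + 1), baseline_scale = 0.05)
  frame <- prsfruit:::simulate_frame(cfg)
  set.seed(99)
  ev <- generate_event_times(cfg, frame$true_linear_predictor,
                             frame$covariates$subcohort)
  expect_true(all(ev$event == 1L))
  u <- 0.05 * ev$followup_years  # shape 1
  expect_gt(stats::ks.test(u, "pexp", 1)$p.value, 0.01)
  # shape 2: scale * T^2 is the same Exp(1) variable
  cfg2 <- cfg; cfg2$weibull_shape <- 2
  set.seed(99)
  ev2 <- generate_event_times(cfg2, frame$true_linear_predictor,
                              frame$covariates$subcohort)
  expect_gt(stats::ks.test(0.05 * ev2$followup_years^2, "pexp", 1)$p.value,
            0.01)
  expect_equal(u, 0.05 * ev2$followup_years^2, tolerance = 1e-10)
})

test_that("a null-effect generator yields hazard ratios near one", {
  cfg <- quick_config(seed = 21L, n = 8000L, n_snps = 30L,
                      effect_mode = "category",
                      true_hr_genetic = c(1, 1), true_hr_fruit = c(1, 1),
                      baseline_scale = 0.01)
  co <- make_test_cohort(cfg)$cohort
  fit <- fit_stratified_cox(co, cox_model_spec("genetic_group", "base",
                                               "genetic"))
  hr <- hazard_ratios(fit, terms = "genetic_group")
  se <- sqrt(diag(fit$cov))[1:2]
  expect_true(all(abs(log(hr$hr)) < 3 * se))
})

test_that("exclusion fixtures hit exact, disjoint counts", {
  cfg <- quick_config(seed = 5L, n = 600L, n_snps = 8L,
                      missing_fruit_n = 7L, prevalent_n = 5L,
                      missing_followup_n = 3L)
  raw <- generate_cohort(cfg)$cohort
  ex <- apply_exclusions(raw)
  expect_identical(ex$audit$n_input, 600L)
  expect_identical(ex$audit$n_missing_fruit, 7L)
  expect_identical(ex$audit$n_prevalent, 5L)
  expect_identical(ex$audit$n_missing_followup, 3L)
  expect_identical(ex$audit$n_analytic, 600L - 15L)
  expect_identical(nrow(ex$cohort), 585L)
})

test_that("fixture counts larger than the cohort are rejected", {
  expect_error(quick_config(seed = 5L, n = 10L, n_snps = 5L,
                            missing_fruit_n = 20L),
               "exceed")
})

test_that("the raw score mean matches its population value", {
  cfg <- quick_config(seed = 13L, n = 6000L, n_snps = 25L)
  panel <- generate_snp_panel(cfg)
  g <- generate_genotypes(cfg, panel)
  prs <- as.numeric(g %*% panel$weight)
  mu <- sum(2 * panel$allele_freq * panel$weight)
  sigma <- sqrt(sum(2 * panel$allele_freq * (1 - panel$allele_freq) *
                      panel$weight^2))
  expect_lt(abs(mean(prs) - mu), 4 * sigma / sqrt(length(prs)))
})

test_that("the polygenic score is approximately normal across seeds", {
  ps <- vapply(1:10, function(s) {
    cfg <- quick_config(seed = s, n = 5000L, n_snps = 60L)
    panel <- generate_snp_panel(cfg)
    g <- generate_genotypes(cfg, panel)
    nortest::ad.test(as.numeric(g %*% panel$weight))$p.value
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.9)
})

test_that("stroke subtypes are drawn in the configured proportions", {
  cfg <- quick_config(seed = 17L, n = 10000L, n_snps = 10L,
                      baseline_scale = 0.02)
  raw <- generate_cohort(cfg)$cohort
  tab <- event_subtype_table(raw)
  expect_identical(unname(tab["total"]),
                   sum(tab[c("ischemic", "hemorrhagic", "both", "unknown")]))
  obs <- tab[c("ischemic", "hemorrhagic", "both", "unknown")] / tab["total"]
  p <- cfg$subtype_probs
  se <- sqrt(p * (1 - p) / tab["total"])
  expect_true(all(abs(obs - p) < 4 * se))
})

test_that("baseline-scale calibration converges and is a fixed point", {
  cfg <- quick_config(seed = 4L, n = 4000L, n_snps = 15L,
                      baseline_scale = 0.0005)
  cal <- calibrate_baseline_scale(cfg, target_rate = 7.7, n_calib = 4000L)
  raw <- generate_cohort(cal)$cohort
  rate <- 1000 * sum(raw$event) / sum(raw$followup_years)
  expect_lt(abs(rate - 7.7) / 7.7, 0.05)
  # an in-tolerance config is returned unchanged
  expect_identical(calibrate_baseline_scale(cal, 7.7, n_calib = 4000L)
                   $baseline_scale,
                   cal$baseline_scale)
  # the rate is monotone in the scale on a fixed seed
  hi <- cal; hi$baseline_scale <- 2 * cal$baseline_scale
  raw_hi <- generate_cohort(hi)$cohort
  expect_gt(sum(raw_hi$event), sum(raw$event))
  # unreachable targets are reported, not silently clamped
  expect_error(calibrate_baseline_scale(cfg, target_rate = 1e6,
                                        n_calib = 2000L),
               "achievable range")
})

test_that("config round-trips through YAML and hashing is stable", {
  cfg <- quick_config(seed = 31L, n = 100L, n_snps = 6L)
  path <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_identical(config_hash(cfg), config_hash(cfg2))
  expect_equal(cfg2$baseline_scale, cfg$baseline_scale)
  pj <- tempfile(fileext = ".json")
  write_generator_config(cfg, pj)
  expect_identical(config_hash(cfg), config_hash(read_generator_config(pj)))
  cfg3 <- cfg; cfg3$seed <- 32L
  expect_false(config_hash(cfg) == config_hash(cfg3))
})

test_that("export drops the oracle columns", {
  cfg <- quick_config(seed = 41L, n = 50L, n_snps = 5L)
  sim <- generate_cohort(cfg)
  dir <- tempfile()
  paths <- export_cohort(sim, dir)
  out <- read_cohort(paths[["cohort"]])
  expect_false(any(c("prs_true", "true_genetic_group", "true_fruit_group",
                     "true_linear_predictor") %in% names(out)))
  g <- read_genotypes(paths[["genotypes"]])
  expect_equal(unname(g), unname(sim$genotypes))
  pan <- read_snp_panel(paths[["panel"]])
  expect_equal(pan$weight, sim$panel$weight, tolerance = 1e-12)
})
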