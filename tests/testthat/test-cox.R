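test_that("the fit agrees with a brute-force partial-likelihood oracle", {
  # small fixture with a tie, evaluated against a direct grid search over
  # the Breslow partial likelihood written from its definition
  time <- c(2, 3, 3, 5, 7, 9, 4, 6)
  event <- c(1, 1, 1, 0, 1, 0, 1, 1)
  x <- c(0.5, -1, 2, 0, 1.5, -0.5, 0.2, -1.2)
  d <- data.frame(followup_years = time, event = event, x = x,
                  age = 50, sex = factor("female",
                                         levels = c("female", "male")),
                  subcohort = 1L)
  sp <- cox_model_spec("x", analysis = "genetic")
  sp$covariates <- character()
  fit <- fit_stratified_cox(d, sp)
  oracle <- breslow_grid_mle(time, event, x)
  expect_equal(unname(fit$beta["x"]), oracle, tolerance = 1e-4)
  # and the maximized log partial likelihood matches
  expect_equal(fit$loglik, breslow_loglik(oracle, time, event, x),
               tolerance = 1e-6)
})

test_that("a constant covariate contributes beta = 0, HR = 1", {
  d <- data.frame(followup_years = c(1, 2, 3, 4, 5),
                  event = c(1, 0, 1, 1, 0),
                  const = 7, x = c(1, 0, 1, 0, 1),
                  subcohort = 1L)
  sp <- cox_model_spec(c("x", "const"), analysis = "genetic")
  sp$covariates <- character()
  fit <- fit_stratified_cox(d, sp)
  expect_equal(unname(fit$beta["const"]), 0)
  expect_equal(fit$cov["const", "const"], 0)
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr[hr$term == "const"], 1)
  # the informative covariate is still estimated
  expect_true(is.finite(fit$beta["x"]))
})

test_that("the baseline at beta = 0 is the Nelson-Aalen estimator", {
  d <- data.frame(followup_years = c(1, 2, 3, 4, 5, 3),
                  event = c(1, 0, 1, 1, 0, 1),
                  const = 1, subcohort = 1L)
  sp <- cox_model_spec("const", analysis = "genetic")
  sp$covariates <- character()
  fit <- fit_stratified_cox(d, sp)
  na <- nelson_aalen(d$followup_years, d$event)
  jumps <- fit$baseline[fit$baseline$time %in% na$time, ]
  expect_equal(jumps$cumhaz, na$cumhaz, tolerance = 1e-12)
})

test_that("stratified and unstratified fits agree under equal baselines", {
  cfg <- quick_config(seed = 15L, n = 20000L, n_snps = 20L,
                      effect_mode = "category",
                      subcohort_scale_mult = c(1, 1, 1),
                      baseline_scale = 0.01)
  co <- make_test_cohort(cfg)$cohort
  sp <- cox_model_spec("genetic_group", "base", "genetic")
  strat <- fit_stratified_cox(co, sp)
  un <- survival::coxph(
    survival::Surv(followup_years, event) ~ genetic_group + age + sex,
    data = co, ties = "breslow")
  expect_equal(unname(strat$beta[1:2]), unname(stats::coef(un)[1:2]),
               tolerance = 0.02)
})

test_that("input validation catches unusable cohorts", {
  d <- data.frame(followup_years = c(1, 2), event = c(0, 0), x = c(0, 1),
                  subcohort = 1L)
  sp <- cox_model_spec("x", analysis = "genetic")
  sp$covariates <- character()
  expect_error(fit_stratified_cox(d[0, ], sp), "empty")
  expect_error(fit_stratified_cox(d, sp), "at least one event")
  d2 <- data.frame(followup_years = c(0, 2, 3), event = c(1, 1, 0),
                   age = c(50, 60, 70), x = c(0, 1, 0), subcohort = 1L)
  sp2 <- sp; sp2$timescale <- "age"
  expect_error(fit_stratified_cox(d2, sp2), "non-positive follow-up")
  expect_error(cox_model_spec("x", strata = "x"), "strata")
})

test_that("perfect separation is reported as an error", {
  # the covariate perfectly orders events before censorings
  d <- data.frame(followup_years = c(1, 2, 3, 10, 11, 12),
                  event = c(1, 1, 1, 0, 0, 0),
                  x = c(0.05, 0.05, 0.05, -0.05, -0.05, -0.05),
                  subcohort = 1L)
  sp <- cox_model_spec("x", analysis = "genetic")
  sp$covariates <- character()
  suppressWarnings(expect_error(fit_stratified_cox(d, sp), "separation"))
})

test_that("Schoenfeld diagnostics match cox.zph and need covariates", {
  cfg <- quick_config(seed = 16L, n = 3000L, n_snps = 10L,
                      baseline_scale = 0.02)
  co <- make_test_cohort(cfg)$cohort
  fit <- fit_stratified_cox(co, cox_model_spec("fruit_group", "base"))
  tab <- schoenfeld_ph_test(fit)
  expect_identical(tab$term[nrow(tab)], "GLOBAL")
  z <- survival::cox.zph(fit$coxph, transform = "km")
  expect_equal(tab$p, unname(z$table[, "p"]), tolerance = 1e-12)
  null_fit <- structure(list(beta = numeric(0)), class = "cox_fit")
  expect_error(schoenfeld_ph_test(null_fit), "no covariates")
})

test_that("the trend test on two categories equals the binary Wald test", {
  cfg <- quick_config(seed = 18L, n = 3000L, n_snps = 10L,
                      baseline_scale = 0.02)
  co <- make_test_cohort(cfg)$cohort
  co$half <- factor(ifelse(co$fruit_g_day > stats::median(co$fruit_g_day),
                           "hi", "lo"), levels = c("lo", "hi"))
  tr <- trend_test(co, "half", "fruit_g_day",
                   cox_model_spec(analysis = "fruit"))
  # with two categories the median recoding is an affine transform of the
  # 0/1 indicator, so the Wald z (and p) must coincide
  co$ind <- as.numeric(co$half == "hi")
  fit <- fit_stratified_cox(co, cox_model_spec("ind", analysis = "fruit"))
  z_ind <- fit$beta["ind"] / sqrt(fit$cov["ind", "ind"])
  expect_equal(tr$p_trend, unname(2 * stats::pnorm(-abs(z_ind))),
               tolerance = 1e-8)
  med <- tr$medians
  expect_equal(tr$beta * (med["hi"] - med["lo"]), fit$beta[["ind"]],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the unadjusted Poisson rate is events over person-years", {
  d <- data.frame(event = c(1L, 0L, 1L, 0L, 0L),
                  followup_years = c(2, 3, 4, 5, 6), subcohort = 1L)
  r <- poisson_adjusted_rates(d, adjust = character())
  expect_equal(r$rate, 1000 * 2 / 20, tolerance = 1e-8)
  expect_identical(r$events, 2L)
  expect_equal(r$person_years, 20)
})

test_that("adjusted rates preserve ordering of a strong group effect", {
  cfg <- quick_config(seed = 19L, n = 8000L, n_snps = 20L,
                      effect_mode = "category",
                      true_hr_genetic = c(1.5, 3), baseline_scale = 0.01)
  co <- make_test_cohort(cfg)$cohort
  r <- poisson_adjusted_rates(co, "genetic_group")
  expect_identical(r$group, c("low", "intermediate", "high"))
  expect_true(all(diff(r$rate) > 0))
  expect_true(all(r$lower < r$rate & r$rate < r$upper))
})

test_that("efron ties are available behind the spec flag", {
  cfg <- quick_config(seed = 20L, n = 2000L, n_snps = 10L,
                      baseline_scale = 0.02)
  co <- make_test_cohort(cfg)$cohort
  sp_b <- cox_model_spec("genetic_group", "base", "genetic")
  sp_e <- cox_model_spec("genetic_group", "base", "genetic", ties = "efron")
  fb <- fit_stratified_cox(co, sp_b)
  fe <- fit_stratified_cox(co, sp_e)
  expect_identical(fe$spec$ties, "efron")
  # continuous times have almost no ties, so estimates nearly coincide
  expect_equal(unname(fe$beta), unname(fb$beta), tolerance = 1e-4)
})
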