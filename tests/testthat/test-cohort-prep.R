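test_that("fruit categories honour their boundaries exactly", {
  lo <- 200 / 7
  x <- c(0, lo - 1e-9, lo, 50, 100, 100 + 1e-9, 150, NA)
  grp <- derive_fruit_group(x)
  expect_identical(as.character(grp),
                   c("low", "low", "mid", "mid", "mid", "high", "high", NA))
  expect_identical(levels(grp), c("low", "mid", "high"))
  expect_false(is.ordered(grp))
  expect_error(derive_fruit_group(-1), "non-negative")
  expect_error(derive_fruit_group(Inf), "finite")
})

test_that("diet score counts ideal components with strict red-meat cut", {
  # all four ideal, with red meat just under the cut
  expect_identical(derive_diet_score(74.99, 125, 200, 3), 4L)
  # red meat exactly at 75 g/day is not ideal
  expect_identical(derive_diet_score(75, 125, 200, 3), 3L)
  # the other three cuts are inclusive
  expect_identical(derive_diet_score(100, 124.99, 199.99, 2.99), 0L)
  expect_identical(derive_diet_score(0, 0, 0, 0), 1L)
  expect_identical(derive_diet_score(c(50, 80), c(200, 0), c(300, 0),
                                     c(5, 0)), c(4L, 0L))
})

test_that("activity level is moderate plus twice vigorous", {
  a <- derive_ideal_activity(c(100, 150, 149, 0), c(30, 0, 0, 75))
  expect_equal(a$activity_level, c(160, 150, 149, 150))
  expect_identical(a$ideal_activity, c(1L, 1L, 0L, 1L))
})

test_that("clinical flags follow the diagnostic cutoffs", {
  f <- derive_clinical_flags(
    sbp = c(139, 140, 120, 120), dbp = c(89, 80, 90, 80),
    bp_meds = c(0, 0, 0, 1),
    glucose_mg_dl = c(126, 125, 100, 100),
    diabetes_treated = c(0, 0, 1, 0),
    total_chol = c(239, 240, 200, 200),
    triglycerides = c(199, 100, 200, 100),
    ldl = c(159, 100, 100, 160),
    hdl = c(40, 50, 50, 39),
    lipid_meds = c(0, 0, 0, 0))
  expect_identical(f$hypertension, c(0L, 1L, 1L, 1L))
  expect_identical(f$diabetes, c(1L, 0L, 1L, 0L))
  expect_identical(f$dyslipidemia, c(0L, 1L, 1L, 1L))
  expect_identical(derive_clinical_flags(120, 80, 0, 100, 0, 200, 100,
                                         100, 39.99, 0)$dyslipidemia, 1L)
})

test_that("BMI is weight over height squared", {
  expect_equal(bmi_from(70, 1.7), 70 / 1.7^2)
  expect_equal(round(bmi_from(70, 1.7), 2), 24.22)
})

test_that("the exclusion cascade counts each row once, in order", {
  raw <- data.frame(
    participant_id = paste0("P", 1:5),
    fruit_g_day = c(NA, 50, 60, NA, 70),
    prevalent_disease = c(1L, 1L, 0L, 0L, 0L),
    followup_years = c(5, 6, NA, NA, 8),
    event = c(0L, 0L, 0L, 0L, 1L),
    # columns required by prepare_cohort for the surviving row
    subcohort = 1L, age = 55, sex = "female", region = "south",
    urban = 0L, education_high = 1L, smoker = 0L, alcohol = 0L,
    moderate_min_wk = 200, vigorous_min_wk = 0, bmi = 24,
    vegetable_g_day = 300, red_meat_g_day = 50, legumes_g_day = 150,
    fish_g_week = 250, tea_times_week = 5, sbp = 120, dbp = 80,
    bp_meds = 0L, glucose_mg_dl = 100, diabetes_treated = 0L,
    total_chol = 200, triglycerides = 100, ldl = 110, hdl = 50,
    lipid_meds = 0L, event_subtype = c(NA, NA, NA, NA, "ischemic"),
    stringsAsFactors = FALSE)
  ex <- apply_exclusions(raw)
  # row 1: missing fruit wins over prevalence; row 2: prevalent;
  # row 3: missing follow-up; row 4: missing fruit wins; row 5 kept
  expect_identical(ex$audit$n_missing_fruit, 2L)
  expect_identical(ex$audit$n_prevalent, 1L)
  expect_identical(ex$audit$n_missing_followup, 1L)
  expect_identical(ex$audit$n_analytic, 1L)
  expect_identical(ex$cohort$participant_id, "P5")
  # conservation: every input row lands in exactly one bucket
  expect_identical(ex$audit$n_missing_fruit + ex$audit$n_prevalent +
                     ex$audit$n_missing_followup + ex$audit$n_analytic,
                   ex$audit$n_input)
})

test_that("excluding everyone yields an empty, flagged analytic set", {
  raw <- data.frame(participant_id = "P1", fruit_g_day = NA_real_,
                    prevalent_disease = 0L, followup_years = 4)
  ex <- apply_exclusions(raw)
  expect_identical(ex$audit$n_analytic, 0L)
  expect_identical(nrow(ex$cohort), 0L)
  expect_s3_class(ex$cohort, "cohort_table")
  expect_error(prepare_cohort(ex$cohort), "empty analytic cohort")
  expect_error(apply_exclusions(data.frame(a = 1)), "lacks exclusion")
})

test_that("derivation is idempotent", {
  cfg <- quick_config(seed = 9L, n = 300L, n_snps = 6L)
  raw <- generate_cohort(cfg)$cohort
  once <- prepare_cohort(raw)
  twice <- prepare_cohort(once)
  expect_identical(once$fruit_group, twice$fruit_group)
  expect_identical(once$diet_score, twice$diet_score)
  expect_identical(once$hypertension, twice$hypertension)
  expect_equal(once$activity_level, twice$activity_level)
})

test_that("missing analysis values after exclusion are an error", {
  cfg <- quick_config(seed = 9L, n = 100L, n_snps = 6L)
  raw <- generate_cohort(cfg)$cohort
  raw$bmi[3] <- NA
  expect_error(prepare_cohort(raw), "missing values.*bmi")
})

test_that("baseline table reproduces a hand-computed chi-square test", {
  cfg <- quick_config(seed = 10L, n = 1500L, n_snps = 6L,
                      baseline_scale = 0.02)
  co <- prepare_cohort(generate_cohort(cfg)$cohort)
  tab <- baseline_table(co)
  expect_s3_class(tab, "baseline_table")
  # smoker row p-value equals the standard 2x2 chi-square by hand
  p_pkg <- tab$p_value[tab$characteristic == "Current smoker"]
  ct <- table(factor(co$event), factor(co$smoker, levels = 0:1))
  expect_equal(p_pkg, stats::chisq.test(ct)$p.value, tolerance = 1e-12)
  # age row equals the Welch t-test
  p_age <- tab$p_value[tab$characteristic == "Age, years"]
  expect_equal(p_age, stats::t.test(co$age ~ factor(co$event))$p.value,
               tolerance = 1e-12)
  expect_error(baseline_table(transform(co, event = 0L)), "two levels")
})

test_that("subtype table counts events and totals consistently", {
  d <- data.frame(event = c(1L, 1L, 1L, 0L, 1L, 1L),
                  event_subtype = c("ischemic", "ischemic", "hemorrhagic",
                                    NA, "both", "unknown"))
  tab <- event_subtype_table(d)
  expect_identical(unname(tab[c("ischemic", "hemorrhagic", "both",
                                "unknown")]), c(2L, 1L, 1L, 1L))
  expect_identical(unname(tab["total"]), 5L)
})
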