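#' Fruit intake categories
#'
#' Tertile-based categories with boundaries read literally from their
#' labels: `low` is < 200 g/week, `mid` is 200 g/week to 100 g/day
#' (closed interval), `high` is strictly > 100 g/day.  The weekly-to-daily
#' conversion factor is fixed at 7, so the lower boundary is
#' 200/7 = 28.5714 g/day.  Every non-negative intake maps to exactly one
#' category; missing intakes stay missing (they are removed by the
#' exclusion cascade, not imputed).
#'
#' @param fruit_g_day Numeric vector of average daily fruit intake (g/day).
#' @return Factor with levels `low`, `mid`, `high` (low is the reference).
#' @export
derive_fruit_group <- function(fruit_g_day) {
  ok <- !is.na(fruit_g_day)
  if (any(fruit_g_day[ok] < 0)) stop("fruit intake must be non-negative")
  if (any(!is.finite(fruit_g_day[ok]))) stop("fruit intake must be finite")
  lo <- 200 / 7
  grp <- rep(NA_character_, length(fruit_g_day))
  grp[ok] <- ifelse(fruit_g_day[ok] < lo, "low",
                    ifelse(fruit_g_day[ok] > 100, "high", "mid"))
  factor(grp, levels = c("low", "mid", "high"))
}

#' Healthy diet score
#'
#' One point for each dietary component at its ideal level: red meat
#' < 75 g/day (strict), legumes >= 125 g/day, fish >= 200 g/week, tea
#' >= 3 times/week.  Scores range 0--4; an ideal diet is a score of at
#' least 2 components.
#'
#' @param red_meat_g_day,legumes_g_day,fish_g_week,tea_times_week
#'   Non-negative numeric vectors.
#' @return Integer vector of scores in 0..4.
#' @export
derive_diet_score <- function(red_meat_g_day, legumes_g_day, fish_g_week,
                              tea_times_week) {
  as.integer((red_meat_g_day < 75) + (legumes_g_day >= 125) +
               (fish_g_week >= 200) + (tea_times_week >= 3))
}

#' Physical activity level and the ideal-activity flag
#'
#' The level sums moderate minutes per week and vigorous minutes per week
#' weighted by 2; the ideal level is at least 150 min/week of moderate
#' activity, 75 min/week of vigorous activity, or an equivalent
#' combination (level >= 150).
#'
#' @param moderate_min_wk,vigorous_min_wk Non-negative numeric vectors.
#' @return Data frame with `activity_level` (moderate-equivalent min/week)
#'   and `ideal_activity` (0/1).
#' @export
derive_ideal_activity <- function(moderate_min_wk, vigorous_min_wk) {
  level <- moderate_min_wk + 2 * vigorous_min_wk
  data.frame(activity_level = level, ideal_activity = as.integer(level >= 150))
}

#' Clinical condition flags
#'
#' Hypertension: systolic BP >= 140 mmHg and/or diastolic BP >= 90 mmHg
#' and/or antihypertensive treatment.  Diabetes: fasting glucose
#' >= 126 mg/dL and/or previously diagnosed/treated diabetes.
#' Dyslipidemia: total cholesterol >= 240 mg/dL, or triglycerides
#' >= 200 mg/dL, or LDL-C >= 160 mg/dL, or HDL-C < 40 mg/dL, or
#' lipid-lowering treatment.
#'
#' @param sbp,dbp Blood pressures, mmHg.
#' @param bp_meds Antihypertensive treatment flag.
#' @param glucose_mg_dl Fasting glucose, mg/dL.
#' @param diabetes_treated Diagnosed or treated diabetes flag.
#' @param total_chol,triglycerides,ldl,hdl Serum lipids, mg/dL.
#' @param lipid_meds Lipid-lowering treatment flag.
#' @return Data frame with 0/1 `hypertension`, `diabetes`, `dyslipidemia`.
#' @export
derive_clinical_flags <- function(sbp, dbp, bp_meds, glucose_mg_dl,
                                  diabetes_treated, total_chol,
                                  triglycerides, ldl, hdl, lipid_meds) {
  data.frame(
    hypertension = as.integer(sbp >= 140 | dbp >= 90 | bp_meds == 1),
    diabetes = as.integer(glucose_mg_dl >= 126 | diabetes_treated == 1),
    dyslipidemia = as.integer(total_chol >= 240 | triglycerides >= 200 |
                                ldl >= 160 | hdl < 40 | lipid_meds == 1))
}

#' Body mass index
#'
#' @param weight_kg,height_m Weight in kilograms and height in metres.
#' @return BMI in kg/m^2.
#' @export
bmi_from <- function(weight_kg, height_m) weight_kg / height_m^2

#' Apply the exclusion cascade and derive the analytic cohort
#'
#' Participants are excluded in a fixed order, each counted once at the
#' first matching rule: (1) missing fruit intake, (2) prevalent
#' cardiovascular disease or cancer, (3) missing follow-up.  The remaining
#' rows get every derived analysis variable (fruit group, diet score,
#' physical activity, clinical flags, vegetable flag) and are returned with
#' an audit of the cascade.
#'
#' @param raw Raw cohort table (as from [generate_cohort()]`$cohort` or a
#'   user file with the documented columns).
#' @return List with `cohort` (the analytic table, class `cohort_table`)
#'   and `audit` (class `exclusion_audit`: n_input, per-rule counts,
#'   n_analytic).
#' @export
apply_exclusions <- function(raw) {
  need <- c("fruit_g_day", "prevalent_disease", "followup_years")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("raw table lacks exclusion columns: ", paste(miss, collapse = ", "))
  n_input <- nrow(raw)
  r1 <- is.na(raw$fruit_g_day)
  r2 <- !r1 & raw$prevalent_disease == 1
  r3 <- !r1 & !r2 & is.na(raw$followup_years)
  keep <- !(r1 | r2 | r3)
  audit <- structure(list(n_input = n_input,
                          n_missing_fruit = sum(r1),
                          n_prevalent = sum(r2),
                          n_missing_followup = sum(r3),
                          n_analytic = sum(keep)),
                     class = "exclusion_audit")
  kept <- raw[keep, , drop = FALSE]
  # an empty analytic set is allowed here (flagged in the audit); stages
  # that cannot run on it raise their own explicit empty-cohort error
  cohort <- if (nrow(kept) == 0L)
    structure(kept, class = c("cohort_table", "data.frame"))
  else prepare_cohort(kept)
  list(cohort = cohort, audit = audit)
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat(sprintf("Exclusion cascade: %d -> %d analytic participants\n",
              x$n_input, x$n_analytic))
  cat(sprintf("  missing fruit intake: %d\n  prevalent disease/cancer: %d\n  missing follow-up: %d\n",
              x$n_missing_fruit, x$n_prevalent, x$n_missing_followup))
  invisible(x)
}

#' Derive every analysis variable on an already-filtered table
#'
#' Idempotent: re-deriving on its own output leaves the derived columns
#' unchanged.
#'
#' @param raw Filtered participant table.
#' @return The table with derived columns appended, class `cohort_table`.
#' @export
prepare_cohort <- function(raw) {
  if (nrow(raw) == 0L)
    stop("empty analytic cohort: every participant was excluded")
  d <- as.data.frame(raw)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$region <- factor(d$region, levels = c("south", "north"))
  d$fruit_group <- derive_fruit_group(d$fruit_g_day)
  d$diet_score <- derive_diet_score(d$red_meat_g_day, d$legumes_g_day,
                                    d$fish_g_week, d$tea_times_week)
  d$ideal_diet <- as.integer(d$diet_score >= 2)
  act <- derive_ideal_activity(d$moderate_min_wk, d$vigorous_min_wk)
  d$activity_level <- act$activity_level
  d$ideal_activity <- act$ideal_activity
  flg <- derive_clinical_flags(d$sbp, d$dbp, d$bp_meds, d$glucose_mg_dl,
                               d$diabetes_treated, d$total_chol,
                               d$triglycerides, d$ldl, d$hdl, d$lipid_meds)
  d[names(flg)] <- flg
  d$vegetable_daily_500 <- as.integer(d$vegetable_g_day >= 500)
  ana <- c("subcohort", "age", "sex", "region", "urban", "education_high",
           "smoker", "alcohol", "activity_level", "bmi", "diet_score",
           "fruit_g_day", "fruit_group", "vegetable_daily_500",
           "hypertension", "diabetes", "dyslipidemia",
           "followup_years", "event")
  bad <- ana[vapply(d[ana], anyNA, logical(1))]
  if (length(bad))
    stop("missing values in analysis columns after exclusions: ",
         paste(bad, collapse = ", "))
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Descriptive baseline table
#'
#' Mean (SD) with a two-sample t-test for continuous variables; n (%) with
#' a chi-square test for dichotomous variables, compared across the levels
#' of a grouping flag (by default incident stroke).
#'
#' @param cohort A `cohort_table`.
#' @param by Name of the 0/1 grouping column (default `"event"`).
#' @return Data frame of class `baseline_table`: one row per
#'   characteristic with per-group summaries and the p-value.
#' @export
baseline_table <- function(cohort, by = "event") {
  g <- factor(cohort[[by]])
  if (nlevels(g) != 2L) stop("grouping variable must have two levels")
  cont <- c(age = "Age, years", bmi = "Body mass index, kg/m2",
            activity_level = "Physical activity, min/week",
            fruit_g_day = "Fruit intake, g/day",
            vegetable_g_day = "Vegetable intake, g/day")
  bin <- c(female = "Female", north = "Northern", urban = "Urban residence",
           education_high = "High school or above", smoker = "Current smoker",
           alcohol = "Alcohol drinker", ideal_activity = "Ideal physical activity",
           ideal_diet = "Ideal diet score", hypertension = "Hypertension",
           diabetes = "Diabetes mellitus", dyslipidemia = "Dyslipidemia")
  cohort$female <- as.integer(cohort$sex == "female")
  cohort$north <- as.integer(cohort$region == "north")
  rows <- list()
  for (v in names(cont)) {
    x <- split(cohort[[v]], g)
    p <- tryCatch(stats::t.test(cohort[[v]] ~ g)$p.value, error = function(e) NA)
    rows[[v]] <- data.frame(
      characteristic = cont[[v]], type = "continuous",
      group0 = sprintf("%.1f ± %.1f", mean(x[[1]]), stats::sd(x[[1]])),
      group1 = sprintf("%.1f ± %.1f", mean(x[[2]]), stats::sd(x[[2]])),
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in names(bin)) {
    tab <- table(g, factor(cohort[[v]], levels = 0:1))
    p <- tryCatch(stats::chisq.test(tab)$p.value, error = function(e) NA)
    rows[[v]] <- data.frame(
      characteristic = bin[[v]], type = "binary",
      group0 = sprintf("%d (%.0f%%)", tab[1, 2], 100 * tab[1, 2] / sum(tab[1, ])),
      group1 = sprintf("%d (%.0f%%)", tab[2, 2], 100 * tab[2, 2] / sum(tab[2, ])),
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[3:4] <- paste0(by, "=", levels(g))
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Summarize first-ever events by stroke subtype
#'
#' @param cohort A `cohort_table` (or any table with `event` and
#'   `event_subtype`).
#' @return Named integer vector of subtype counts plus a `total` entry
#'   equal to their sum.
#' @export
event_subtype_table <- function(cohort) {
  ev <- cohort[cohort$event == 1L, , drop = FALSE]
  lv <- c("ischemic", "hemorrhagic", "both", "unknown")
  counts <- table(factor(ev$event_subtype, levels = lv))
  c(stats::setNames(as.integer(counts), lv), total = nrow(ev))
}

#' Read a raw cohort table from delimited text
#'
#' @param path CSV path matching the generator's export format.
#' @return Data frame of raw participant rows.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
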