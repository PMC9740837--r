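#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the cohort simulator: panel size and allele
#' frequencies, covariate marginals, the true hazard structure (continuous
#' polygenic-score effect or category/cell effects), the Weibull baseline,
#' competing death, administrative censoring, and the exclusion-cascade
#' fixture counts.  The seed fully determines the generated tables.
#'
#' The defaults describe a three-cohort Chinese adult population: mean age 55
#' (SD 10) years, 58% female, mean fruit intake near 83 g/day with tertile
#' boundaries close to 200 g/week and 100 g/day, crude stroke incidence near
#' 7.7 per 1000 person-years under administrative censoring at 10--13 years,
#' and true hazard ratios of 1.19/1.51 for intermediate/high genetic risk and
#' 0.81/0.69 for intermediate/high fruit intake.
#'
#' @param n_participants Number of rows to simulate.
#' @param n_snps Number of biallelic SNPs in the risk panel.
#' @param seed Integer seed; identical configs give bit-identical tables.
#' @param allele_freq_range Range (open interval of (0,1)) for risk-allele
#'   frequencies when the panel is drawn rather than supplied.
#' @param weight_sd Spread of the per-SNP weights (half-normal).
#' @param n_subcohorts Number of sub-cohorts (strata for the Cox models).
#' @param age_mean_sd Mean and SD of baseline age in years.
#' @param prop_female Proportion of women.
#' @param fruit_mixture List with `zero_prob`, `meanlog`, `sdlog`: a
#'   point mass of rare fruit consumers plus a lognormal for the rest.
#' @param covariate_params List of marginals for the remaining covariates;
#'   see [default_covariate_params()].
#' @param effect_mode `"continuous"` (hazard loads on the standardized
#'   polygenic score) or `"category"` (hazard loads on the genetic risk
#'   group, enabling exact recovery tests).
#' @param prs_loghr Log hazard ratio per SD of the polygenic score
#'   (continuous mode).
#' @param true_hr_genetic Hazard ratios (intermediate, high) vs low genetic
#'   risk (category mode).
#' @param true_hr_fruit Hazard ratios (intermediate, high) vs low fruit
#'   intake.
#' @param true_hr_fruit_by_group Optional 3x2 matrix of fruit hazard ratios
#'   (columns: intermediate, high fruit) specific to each genetic risk group
#'   (rows: low, intermediate, high); overrides `true_hr_fruit`.
#' @param true_log_interaction Extra log hazard added to the
#'   high-genetic-risk, low-fruit cell; 0 means exactly multiplicative.
#' @param cell_loghr Optional 3x3 matrix of log hazard ratios over genetic
#'   group (rows: low/intermediate/high) by fruit group (columns:
#'   low/mid/high), relative to the (low genetic, low fruit) cell; overrides
#'   all of the above in category mode.
#' @param covariate_loghr Named vector of log hazard ratios for adjustment
#'   covariates entering the true hazard (default: age per year and male sex).
#' @param weibull_shape Weibull shape of the baseline stroke hazard.
#' @param baseline_scale Weibull scale (cumulative baseline hazard is
#'   `scale * t^shape`); calibrated by [calibrate_baseline_scale()].
#' @param subcohort_scale_mult Per-sub-cohort multipliers of the baseline
#'   scale, making cohort stratification non-trivial.
#' @param admin_censor_years Uniform window (min, max) in years for
#'   administrative censoring.
#' @param death_rate Constant per-year hazard of competing non-stroke death.
#' @param missing_fruit_n,prevalent_n,missing_followup_n Counts of rows to
#'   flag for the exclusion-cascade fixture (disjoint, in this order).
#' @param subtype_probs Probabilities over stroke subtypes
#'   (ischemic, hemorrhagic, both, unknown); must sum to 1.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_cohort()], [calibrate_baseline_scale()]
#' @export
generator_config <- function(n_participants = 35000,
                             n_snps = 534L,
                             seed = 1L,
                             allele_freq_range = c(0.05, 0.95),
                             weight_sd = 0.04,
                             n_subcohorts = 3L,
                             age_mean_sd = c(55, 10),
                             prop_female = 0.58,
                             fruit_mixture = list(zero_prob = 0.08,
                                                  meanlog = 4.05,
                                                  sdlog = 0.94),
                             covariate_params = default_covariate_params(),
                             effect_mode = c("continuous", "category"),
                             prs_loghr = log(1.51) / 2.8,
                             true_hr_genetic = c(1.19, 1.51),
                             true_hr_fruit = c(0.81, 0.69),
                             true_hr_fruit_by_group = NULL,
                             true_log_interaction = 0,
                             cell_loghr = NULL,
                             covariate_loghr = c(age = 0.05, male = 0.30),
                             weibull_shape = 1,
                             baseline_scale = 0.00718,
                             subcohort_scale_mult = c(0.8, 1.0, 1.25),
                             admin_censor_years = c(10, 13),
                             death_rate = 0.008,
                             missing_fruit_n = 0L,
                             prevalent_n = 0L,
                             missing_followup_n = 0L,
                             subtype_probs = c(ischemic = 1834,
                                               hemorrhagic = 439,
                                               both = 55,
                                               unknown = 258) / 2586) {
  effect_mode <- match.arg(effect_mode)
  cfg <- list(
    n_participants = as.integer(n_participants), n_snps = as.integer(n_snps),
    seed = as.integer(seed), allele_freq_range = allele_freq_range,
    weight_sd = weight_sd, n_subcohorts = as.integer(n_subcohorts),
    age_mean_sd = age_mean_sd, prop_female = prop_female,
    fruit_mixture = fruit_mixture, covariate_params = covariate_params,
    effect_mode = effect_mode, prs_loghr = prs_loghr,
    true_hr_genetic = true_hr_genetic, true_hr_fruit = true_hr_fruit,
    true_hr_fruit_by_group = true_hr_fruit_by_group,
    true_log_interaction = true_log_interaction, cell_loghr = cell_loghr,
    covariate_loghr = covariate_loghr, weibull_shape = weibull_shape,
    baseline_scale = baseline_scale,
    subcohort_scale_mult = subcohort_scale_mult,
    admin_censor_years = admin_censor_years, death_rate = death_rate,
    missing_fruit_n = as.integer(missing_fruit_n),
    prevalent_n = as.integer(prevalent_n),
    missing_followup_n = as.integer(missing_followup_n),
    subtype_probs = subtype_probs)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' Default covariate marginals for the synthetic cohort
#'
#' Means, SDs and proportions chosen to land near the descriptive
#' characteristics of a middle-aged Chinese cohort: roughly half northern and
#' half with high-school education, 17% urban, 23% current smokers and
#' drinkers, BMI 24 (SD 4) kg/m^2, vegetable intake 335 (SD 157) g/day, and
#' blood-pressure/glucose/lipid marginals giving hypertension near 38%,
#' diabetes near 9% and dyslipidemia near 33%.
#'
#' @return A named list consumed by [generator_config()].
#' @export
default_covariate_params <- function() {
  list(
    prop_north = 0.50, prop_urban = 0.17, prop_highschool = 0.47,
    prop_smoker = 0.23, prop_alcohol = 0.23,
    bmi_mean_sd = c(24, 4),
    vegetable_mean_sd = c(335, 157),
    # weekly physical activity: moderate lognormal + vigorous in a minority
    moderate_meanlog_sdlog = c(4.9, 0.9), prop_vigorous = 0.25,
    vigorous_meanlog_sdlog = c(4.2, 0.7),
    # diet components (per-day or per-week as in the score definition)
    red_meat_meanlog_sdlog = c(4.0, 0.7),    # g/day, ideal < 75
    legumes_meanlog_sdlog = c(4.1, 1.0),     # g/day, ideal >= 125
    fish_meanlog_sdlog = c(4.0, 1.3),        # g/week, ideal >= 200
    tea_times_meanlog_sdlog = c(0.7, 1.3),   # times/week, ideal >= 3
    prop_tea_never = 0.35,
    # clinical measurements
    sbp_mean_sd = c(129, 19), dbp_mean_sd = c(79, 11),
    prop_bp_meds = 0.12,
    glucose_meanlog_sdlog = c(log(97), 0.17),   # mg/dL, threshold 126
    prop_diab_treated = 0.025,
    chol_mean_sd = c(200, 36),                  # mg/dL, threshold 240
    trig_meanlog_sdlog = c(log(115), 0.50),     # mg/dL, threshold 200
    ldl_mean_sd = c(118, 30), hdl_mean_sd = c(51, 12),
    prop_lipid_meds = 0.02)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_participants < 1L) stop("n_participants must be positive")
  fr <- cfg$allele_freq_range
  if (length(fr) != 2L || any(!is.finite(fr)) || fr[1] <= 0 || fr[2] >= 1 ||
      fr[1] > fr[2])
    stop("allele_freq_range must lie inside the open interval (0, 1)")
  if (abs(sum(cfg$subtype_probs) - 1) > 1e-8)
    stop("subtype_probs must sum to 1")
  if (length(cfg$subtype_probs) != 4L)
    stop("subtype_probs must have 4 entries (ischemic, hemorrhagic, both, unknown)")
  if (!is.finite(cfg$weibull_shape) || cfg$weibull_shape <= 0)
    stop("weibull_shape must be strictly positive")
  if (!is.finite(cfg$baseline_scale) || cfg$baseline_scale <= 0)
    stop("baseline_scale must be strictly positive")
  if (any(cfg$subcohort_scale_mult <= 0))
    stop("subcohort_scale_mult must be strictly positive")
  if (length(cfg$subcohort_scale_mult) != cfg$n_subcohorts)
    stop("subcohort_scale_mult must have one entry per sub-cohort")
  if (cfg$death_rate < 0) stop("death_rate must be non-negative")
  ac <- cfg$admin_censor_years
  if (length(ac) != 2L || ac[1] <= 0 || ac[1] > ac[2])
    stop("admin_censor_years must be a positive (min, max) window")
  nx <- cfg$missing_fruit_n + cfg$prevalent_n + cfg$missing_followup_n
  if (nx > cfg$n_participants)
    stop("exclusion fixture counts exceed n_participants")
  if (!is.null(cfg$cell_loghr) &&
      !(is.matrix(cfg$cell_loghr) && all(dim(cfg$cell_loghr) == c(3, 3))))
    stop("cell_loghr must be a 3x3 matrix (genetic group x fruit group)")
  if (!is.null(cfg$true_hr_fruit_by_group) &&
      !(is.matrix(cfg$true_hr_fruit_by_group) &&
        all(dim(cfg$true_hr_fruit_by_group) == c(3, 2))))
    stop("true_hr_fruit_by_group must be a 3x2 matrix")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  n = %d participants, %d SNPs, %d sub-cohorts, seed %d\n",
              x$n_participants, x$n_snps, x$n_subcohorts, x$seed))
  cat(sprintf("  effect mode: %s; Weibull shape %.3g, baseline scale %.4g\n",
              x$effect_mode, x$weibull_shape, x$baseline_scale))
  cat(sprintf("  censoring U(%g, %g) years; competing death %.3g/yr\n",
              x$admin_censor_years[1], x$admin_censor_years[2], x$death_rate))
  invisible(x)
}

#' Hazard-cell matrix implied by a configuration (category mode)
#'
#' Expands the main-effect hazard ratios (and any stratum-specific fruit
#' effects or interaction term) into the full 3x3 matrix of log hazard
#' ratios over genetic group by fruit group, relative to the
#' (low genetic, low fruit) cell.  A supplied `cell_loghr` wins outright.
#'
#' @param cfg A [generator_config()].
#' @return A 3x3 numeric matrix with dimnames.
#' @export
config_cell_loghr <- function(cfg) {
  gl <- c("low", "intermediate", "high")
  fl <- c("low", "mid", "high")
  if (!is.null(cfg$cell_loghr)) {
    m <- cfg$cell_loghr
  } else {
    g <- c(0, log(cfg$true_hr_genetic))
    if (!is.null(cfg$true_hr_fruit_by_group)) {
      f <- cbind(0, log(cfg$true_hr_fruit_by_group))
      m <- matrix(g, 3, 3) + f
    } else {
      f <- c(0, log(cfg$true_hr_fruit))
      m <- outer(g, f, "+")
    }
    m[3, 1] <- m[3, 1] + cfg$true_log_interaction
  }
  dimnames(m) <- list(genetic = gl, fruit = fl)
  m
}

#' Serialize / restore a generator configuration
#'
#' Configs round-trip through YAML (or JSON by extension) so a run can be
#' reproduced from its logged file.  A short hash of the canonical config is
#' recorded in generated tables' attributes and in pipeline manifests.
#'
#' @param cfg A [generator_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns the restored config.
#' @export
write_generator_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$cell_loghr)) x$cell_loghr <- as.vector(x$cell_loghr)
  if (!is.null(x$true_hr_fruit_by_group))
    x$true_hr_fruit_by_group <- as.vector(x$true_hr_fruit_by_group)
  # named numeric vectors serialize as maps (lists), not sequences, so the
  # names survive the round trip
  x$covariate_loghr <- as.list(x$covariate_loghr)
  x$subtype_probs <- as.list(x$subtype_probs)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  } else {
    # full double precision so the config (and its hash) round-trips exactly
    yaml::write_yaml(x, path, precision = 17L)
  }
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  # JSON reads whole numbers back as integers; restore doubles everywhere
  # (generator_config re-coerces its genuinely integer fields itself)
  x <- rapply(x, function(v) if (is.integer(v)) as.double(v) else v,
              how = "replace")
  # JSON writes absent optional fields as empty objects; treat those as NULL
  x$cell_loghr <- if (length(x$cell_loghr))
    matrix(unlist(x$cell_loghr), 3, 3) else NULL
  x$true_hr_fruit_by_group <- if (length(x$true_hr_fruit_by_group))
    matrix(unlist(x$true_hr_fruit_by_group), 3, 2) else NULL
  x$covariate_loghr <- unlist(x$covariate_loghr)
  x$subtype_probs <- unlist(x$subtype_probs)
  do.call(generator_config, x[setdiff(names(x), character())])
}

#' @rdname write_generator_config
#' @export
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 15)),
             collapse = "\n")
  # 31-ary rolling hash mod 2^31-1; stable across sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
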