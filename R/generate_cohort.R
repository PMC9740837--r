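#' Simulate baseline covariates
#'
#' Draws demographics, lifestyle, diet components and clinical measurements
#' from the marginals in `cfg$covariate_params`, independently of genotype
#' and fruit intake.  Fruit intake itself is a two-part mixture: a point
#' mass of rare consumers (intake 0) plus a lognormal, defaulted so the mean
#' lands near 83 g/day and the tertile boundaries near 200 g/week and
#' 100 g/day.
#'
#' @param cfg A [generator_config()].
#' @param n Number of rows (defaults to `cfg$n_participants`).
#' @return Data frame of raw covariates, one row per participant.
#' @keywords internal
generate_covariates <- function(cfg, n = cfg$n_participants) {
  p <- cfg$covariate_params
  rb <- function(prob) stats::rbinom(n, 1L, prob)
  rn <- function(ms) stats::rnorm(n, ms[1], ms[2])
  rl <- function(ms) stats::rlnorm(n, ms[1], ms[2])

  fruit <- rl(c(cfg$fruit_mixture$meanlog, cfg$fruit_mixture$sdlog))
  fruit[rb(cfg$fruit_mixture$zero_prob) == 1L] <- 0

  data.frame(
    subcohort = sample.int(cfg$n_subcohorts, n, replace = TRUE),
    age = round(rn(cfg$age_mean_sd), 1),
    sex = ifelse(rb(cfg$prop_female) == 1L, "female", "male"),
    region = ifelse(rb(p$prop_north) == 1L, "north", "south"),
    urban = rb(p$prop_urban),
    education_high = rb(p$prop_highschool),
    smoker = rb(p$prop_smoker),
    alcohol = rb(p$prop_alcohol),
    moderate_min_wk = rl(p$moderate_meanlog_sdlog),
    vigorous_min_wk = rb(p$prop_vigorous) * rl(p$vigorous_meanlog_sdlog),
    bmi = pmax(14, rn(p$bmi_mean_sd)),
    vegetable_g_day = pmax(0, rn(p$vegetable_mean_sd)),
    red_meat_g_day = rl(p$red_meat_meanlog_sdlog),
    legumes_g_day = rl(p$legumes_meanlog_sdlog),
    fish_g_week = rl(p$fish_meanlog_sdlog),
    tea_times_week = ifelse(rb(p$prop_tea_never) == 1L, 0,
                            rl(p$tea_times_meanlog_sdlog)),
    sbp = rn(p$sbp_mean_sd),
    dbp = rn(p$dbp_mean_sd),
    bp_meds = rb(p$prop_bp_meds),
    glucose_mg_dl = rl(p$glucose_meanlog_sdlog),
    diabetes_treated = rb(p$prop_diab_treated),
    total_chol = rn(p$chol_mean_sd),
    triglycerides = rl(p$trig_meanlog_sdlog),
    ldl = rn(p$ldl_mean_sd),
    hdl = rn(p$hdl_mean_sd),
    lipid_meds = rb(p$prop_lipid_meds),
    fruit_g_day = fruit,
    stringsAsFactors = FALSE)
}

# Everything deterministic up to (but excluding) the event-time draws:
# panel, genotypes, covariates, polygenic score, true exposure groups and
# the true linear predictor.  Split out so calibration can re-draw event
# times on a fixed frame.
simulate_frame <- function(cfg) {
  validate_generator_config(cfg)
  panel <- generate_snp_panel(cfg)
  genotypes <- generate_genotypes(cfg, panel)
  set.seed(cfg$seed + 2L)
  cov <- generate_covariates(cfg)

  prs_raw <- as.numeric(genotypes %*% panel$weight)
  prs_std <- (prs_raw - mean(prs_raw)) / stats::sd(prs_raw)
  ggrp <- assign_genetic_groups(prs_raw)
  fgrp <- derive_fruit_group(cov$fruit_g_day)

  eta <- cfg$covariate_loghr[["age"]] * (cov$age - cfg$age_mean_sd[1]) +
    cfg$covariate_loghr[["male"]] * (cov$sex == "male")
  if (cfg$effect_mode == "category") {
    cell <- config_cell_loghr(cfg)
    eta <- eta + cell[cbind(as.integer(ggrp), as.integer(fgrp))]
  } else {
    f <- c(0, log(cfg$true_hr_fruit))
    eta <- eta + cfg$prs_loghr * prs_std + f[as.integer(fgrp)] +
      cfg$true_log_interaction * (ggrp == "high" & fgrp == "low")
  }

  list(panel = panel, genotypes = genotypes, covariates = cov,
       prs_raw = prs_raw, prs_std = prs_std,
       true_genetic_group = ggrp, true_fruit_group = fgrp,
       true_linear_predictor = eta)
}

#' Simulate observed follow-up under proportional hazards
#'
#' Latent stroke times follow a Weibull proportional-hazards model with
#' cumulative baseline hazard `scale * t^shape` (per-sub-cohort scale
#' multipliers), drawn by inverse transform; competing non-stroke death is
#' exponential; administrative censoring is uniform on the configured
#' window.  The observed time is the minimum of the three, with flags set
#' accordingly, and stroke subtypes are multinomial over
#' `cfg$subtype_probs`.
#'
#' @param cfg A [generator_config()] (shape, scale, censoring, death rate,
#'   subtype probabilities are read from it).
#' @param linear_predictor Finite numeric vector of true log hazard ratios.
#' @param subcohort Integer vector of sub-cohort labels (scale multipliers);
#'   defaults to sub-cohort 1 for everyone.
#' @param baseline_scale Optional override of `cfg$baseline_scale`.
#' @param latent Optional list of pre-drawn `(u_event, t_death, t_censor,
#'   u_subtype)` draws, used by the calibration bisection so only the scale
#'   changes between evaluations.
#' @return Data frame with `followup_years`, `event`, `death`,
#'   `event_subtype` (NA for non-events).
#' @export
generate_event_times <- function(cfg, linear_predictor,
                                 subcohort = rep(1L, length(linear_predictor)),
                                 baseline_scale = cfg$baseline_scale,
                                 latent = NULL) {
  if (any(!is.finite(linear_predictor)))
    stop("linear_predictor must be finite")
  if (!is.finite(cfg$weibull_shape) || cfg$weibull_shape <= 0 ||
      !is.finite(baseline_scale) || baseline_scale <= 0)
    stop("Weibull shape and scale must be strictly positive")
  n <- length(linear_predictor)
  if (is.null(latent)) latent <- draw_event_latents(cfg, n)
  scale_i <- baseline_scale * cfg$subcohort_scale_mult[subcohort]
  t_event <- (latent$u_event / (scale_i * exp(linear_predictor)))^
    (1 / cfg$weibull_shape)
  obs <- pmin(t_event, latent$t_death, latent$t_censor)
  event <- as.integer(obs == t_event)
  death <- as.integer(obs == latent$t_death & event == 0L)
  subtype <- rep(NA_character_, n)
  lab <- names(cfg$subtype_probs)
  idx <- findInterval(latent$u_subtype, cumsum(cfg$subtype_probs),
                      left.open = TRUE) + 1L
  subtype[event == 1L] <- lab[pmin(idx, 4L)][event == 1L]
  data.frame(followup_years = obs, event = event, death = death,
             event_subtype = subtype, stringsAsFactors = FALSE)
}

draw_event_latents <- function(cfg, n) {
  list(u_event = stats::rexp(n),
       t_death = if (cfg$death_rate > 0) stats::rexp(n, cfg$death_rate)
                 else rep(Inf, n),
       t_censor = stats::runif(n, cfg$admin_censor_years[1],
                               cfg$admin_censor_years[2]),
       u_subtype = stats::runif(n))
}

#' Generate a complete raw synthetic cohort
#'
#' Runs the whole generator: SNP panel, Hardy-Weinberg genotypes, baseline
#' covariates, true polygenic score and exposure groups, proportional-
#' hazards event times, and (optionally) exclusion-cascade fixtures.  The
#' seed fully determines every table.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `synthetic_cohort` with elements `cohort` (raw
#'   participant table including the oracle columns `true_linear_predictor`,
#'   `true_genetic_group`, `true_fruit_group`, dropped on export),
#'   `genotypes`, `panel` and `config`.
#' @export
generate_cohort <- function(cfg) {
  frame <- simulate_frame(cfg)
  set.seed(cfg$seed + 3L)
  ev <- generate_event_times(cfg, frame$true_linear_predictor,
                             frame$covariates$subcohort)
  raw <- data.frame(participant_id = sprintf("P%07d",
                                             seq_len(cfg$n_participants)),
                    frame$covariates, ev,
                    prevalent_disease = 0L,
                    prs_true = frame$prs_raw,
                    true_genetic_group = frame$true_genetic_group,
                    true_fruit_group = frame$true_fruit_group,
                    true_linear_predictor = frame$true_linear_predictor,
                    stringsAsFactors = FALSE)
  rownames(frame$genotypes) <- raw$participant_id
  raw <- inject_exclusion_fixtures(raw, cfg)
  attr(raw, "config_hash") <- config_hash(cfg)
  structure(list(cohort = raw, genotypes = frame$genotypes,
                 panel = frame$panel, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d SNPs (seed %d, config %s)\n",
              nrow(x$cohort), ncol(x$genotypes), x$config$seed,
              attr(x$cohort, "config_hash")))
  cat(sprintf("  events: %d strokes, %d competing deaths\n",
              sum(x$cohort$event, na.rm = TRUE),
              sum(x$cohort$death, na.rm = TRUE)))
  invisible(x)
}

#' Flag rows for the exclusion-cascade fixture
#'
#' Marks three disjoint participant sets, in order of precedence: missing
#' fruit intake, prevalent cardiovascular disease or cancer, and missing
#' follow-up, so the downstream exclusion cascade can be exercised with
#' known counts.
#'
#' @param raw Raw cohort table from [generate_cohort()].
#' @param cfg The [generator_config()] holding `missing_fruit_n`,
#'   `prevalent_n`, `missing_followup_n`.
#' @return The table with fruit/follow-up set missing and prevalence flags
#'   applied on disjoint random rows.
#' @export
inject_exclusion_fixtures <- function(raw, cfg) {
  ntot <- cfg$missing_fruit_n + cfg$prevalent_n + cfg$missing_followup_n
  if (ntot == 0L) return(raw)
  if (ntot > nrow(raw))
    stop("exclusion fixture counts exceed the number of rows")
  set.seed(cfg$seed + 4L)
  idx <- sample.int(nrow(raw), ntot)
  i1 <- idx[seq_len(cfg$missing_fruit_n)]
  i2 <- idx[cfg$missing_fruit_n + seq_len(cfg$prevalent_n)]
  i3 <- idx[cfg$missing_fruit_n + cfg$prevalent_n +
              seq_len(cfg$missing_followup_n)]
  raw$fruit_g_day[i1] <- NA_real_
  raw$prevalent_disease[i2] <- 1L
  raw$followup_years[i3] <- NA_real_
  raw
}

#' Calibrate the baseline hazard scale to a target crude incidence
#'
#' Monotone bisection on the Weibull baseline scale until the generated
#' crude stroke incidence (events per 1000 person-years) is within
#' `tol_rel` of `target_rate`.  The search re-draws event times on a fixed
#' covariate/latent frame, so the rate is an exactly monotone function of
#' the scale.
#'
#' @param cfg A [generator_config()].
#' @param target_rate Target crude incidence, events per 1000 person-years.
#' @param tol_rel Relative tolerance (default 5%).
#' @param n_calib Sample size used during calibration (capped at
#'   `cfg$n_participants`).
#' @param bracket Search interval for the scale.
#' @return The config with `baseline_scale` replaced by the calibrated
#'   value (unchanged if the current scale already meets the tolerance).
#' @export
calibrate_baseline_scale <- function(cfg, target_rate = 7.7, tol_rel = 0.05,
                                     n_calib = 20000L,
                                     bracket = c(1e-5, 0.2)) {
  if (!is.finite(target_rate) || target_rate <= 0)
    stop("target_rate must be positive")
  ccfg <- cfg
  ccfg$n_participants <- as.integer(min(cfg$n_participants, n_calib))
  ccfg$missing_fruit_n <- ccfg$prevalent_n <- ccfg$missing_followup_n <- 0L
  frame <- simulate_frame(ccfg)
  set.seed(ccfg$seed + 3L)
  latent <- draw_event_latents(ccfg, ccfg$n_participants)
  rate_at <- function(scale) {
    ev <- generate_event_times(ccfg, frame$true_linear_predictor,
                               frame$covariates$subcohort,
                               baseline_scale = scale, latent = latent)
    1000 * sum(ev$event) / sum(ev$followup_years)
  }
  r0 <- rate_at(cfg$baseline_scale)
  if (abs(r0 - target_rate) <= tol_rel * target_rate) return(cfg)
  lo <- bracket[1]; hi <- bracket[2]
  rlo <- rate_at(lo); rhi <- rate_at(hi)
  if (rlo > target_rate || rhi < target_rate)
    stop(sprintf(
      "target rate %.3g outside achievable range [%.3g, %.3g] per 1000 PY",
      target_rate, rlo, rhi))
  for (i in 1:60) {
    mid <- sqrt(lo * hi)   # bisect on the log scale
    rmid <- rate_at(mid)
    if (abs(rmid - target_rate) <= 0.25 * tol_rel * target_rate) break
    if (rmid < target_rate) lo <- mid else hi <- mid
  }
  cfg$baseline_scale <- mid
  cfg
}

#' Export a cohort for external analysis
#'
#' Writes the participant table as UTF-8 comma-delimited text with a header
#' row, dropping the generator's oracle columns (`true_*`, `prs_true`), plus
#' the genotype matrix and SNP panel.  The config (with seed) is logged next
#' to the tables.
#'
#' @param sim A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
export_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- setdiff(names(sim$cohort),
                  c("prs_true", "true_genetic_group", "true_fruit_group",
                    "true_linear_predictor"))
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             panel = file.path(dir, "snp_panel.csv"),
             config = file.path(dir, "generator_config.yaml"))
  utils::write.csv(sim$cohort[, keep], paths["cohort"], row.names = FALSE)
  write_genotypes(sim$genotypes, paths["genotypes"])
  write_snp_panel(sim$panel, paths["panel"])
  write_generator_config(sim$config, paths["config"])
  invisible(paths)
}
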