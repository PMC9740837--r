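#' Cox model specifications
#'
#' Declares the adjustment tier, stratification, timescale and tie handling
#' for a cohort-stratified Cox fit.  Two tiers are defined: the `base`
#' model adjusts for age and sex in genetic-risk analyses, and for age,
#' sex, region, urbanization and education in fruit-intake analyses; the
#' `full` model further adds current smoking, alcohol drinking, physical
#' activity, BMI, diet score and the daily-vegetable flag.  Ties are
#' handled by Breslow's approximation by default (Efron available behind
#' the flag).
#'
#' @param exposure Character vector of exposure terms (e.g.
#'   `"genetic_group"`, `"fruit_group"`, or custom column names); may be
#'   empty for a covariates-only fit.
#' @param tier `"base"` or `"full"` adjustment.
#' @param analysis `"genetic"` or `"fruit"`: which base covariate set
#'   applies.
#' @param strata Stratification variable (sub-cohort).
#' @param timescale `"study"` (time-on-study) or `"age"` (age as the
#'   timescale with left-truncated entry at baseline age).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param robust Use a robust sandwich variance (not the default; ordinary
#'   Wald intervals are reported unless asked).
#' @param extra Additional adjustment terms appended to the tier set.
#' @return A list of class `cox_model_spec`.
#' @export
cox_model_spec <- function(exposure = character(),
                           tier = c("base", "full"),
                           analysis = c("fruit", "genetic"),
                           strata = "subcohort",
                           timescale = c("study", "age"),
                           ties = c("breslow", "efron"),
                           robust = FALSE,
                           extra = character()) {
  tier <- match.arg(tier)
  analysis <- match.arg(analysis)
  base_cov <- if (analysis == "genetic") c("age", "sex")
              else c("age", "sex", "region", "urban", "education_high")
  full_add <- c("smoker", "alcohol", "activity_level", "bmi", "diet_score",
                "vegetable_daily_500")
  covariates <- unique(c(if (tier == "full")
                           c("age", "sex", "region", "urban",
                             "education_high", full_add)
                         else base_cov, extra))
  if (strata %in% c(exposure, covariates))
    stop("the strata variable cannot also be a covariate")
  structure(list(exposure = exposure, covariates = covariates, tier = tier,
                 analysis = analysis, strata = strata,
                 timescale = match.arg(timescale), ties = match.arg(ties),
                 robust = robust),
            class = "cox_model_spec")
}

spec_formula <- function(spec) {
  lhs <- if (spec$timescale == "age")
    "survival::Surv(age, age + followup_years, event)"
  else "survival::Surv(followup_years, event)"
  rhs <- c(spec$exposure, spec$covariates,
           sprintf("survival::strata(%s)", spec$strata))
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

#' Fit a cohort-stratified Cox proportional-hazards model
#'
#' Maximizes the stratified partial likelihood (Breslow ties,
#' Newton-Raphson with tight convergence tolerances, at most 50
#' iterations) and extracts the coefficient vector, covariance matrix,
#' log partial likelihood and the per-stratum Breslow cumulative baseline
#' hazard evaluated at covariate value zero.  Hazard ratios and 95% Wald
#' intervals are `exp(beta +/- 1.96 se)`.
#'
#' Monotone-likelihood separation is detected through diverging
#' coefficients (|beta| > 20) and reported as an error, as is
#' non-convergence within the iteration budget.
#'
#' @param cohort A `cohort_table`.
#' @param spec A [cox_model_spec()].
#' @return Object of class `cox_fit`: `beta`, `cov`, `loglik`,
#'   `n_events`, `baseline` (data frame: time, cumhaz, strata),
#'   `convergence`, `spec`, and the underlying `coxph` fit.
#' @export
fit_stratified_cox <- function(cohort, spec) {
  stopifnot(inherits(spec, "cox_model_spec"))
  if (nrow(cohort) == 0L) stop("empty analytic cohort: nothing to fit")
  if (spec$timescale == "age" && any(cohort$followup_years <= 0))
    stop("entry age must precede exit age (non-positive follow-up)")
  ev_by_stratum <- tapply(cohort$event, cohort[[spec$strata]], sum)
  if (any(is.na(ev_by_stratum)) || any(ev_by_stratum < 1))
    stop("every stratum needs at least one event")
  # a constant covariate carries no information: its partial-likelihood
  # maximizer is beta = 0 with zero curvature, so report exactly that
  # rather than letting the model matrix go singular
  terms_all <- c(spec$exposure, spec$covariates)
  zero_info <- terms_all[vapply(terms_all, function(v)
    length(unique(cohort[[v]])) == 1L, logical(1))]
  spec$exposure <- setdiff(spec$exposure, zero_info)
  spec$covariates <- setdiff(spec$covariates, zero_info)
  f <- spec_formula(spec)
  # survfit/cox.zph re-evaluate the call later: keep data reachable from
  # the formula environment
  environment(f) <- environment()
  fit <- survival::coxph(
    f, data = cohort, ties = spec$ties,
    robust = spec$robust,
    control = survival::coxph.control(eps = 1e-10, toler.chol = 1e-12,
                                      iter.max = 50))
  cf <- stats::coef(fit)
  if (is.null(cf)) cf <- numeric(0)
  if (anyNA(cf))
    stop("singular model matrix: a covariate carries no information")
  if (any(abs(cf) > 20))
    stop("separation detected (monotone partial likelihood): |beta| > 20 for ",
         paste(names(cf)[abs(cf) > 20], collapse = ", "))
  bh <- survival::basehaz(fit, centered = FALSE)
  if (is.null(bh$strata)) {
    # single stratum: basehaz drops the strata column; restore the
    # "<var>=<value>" label so downstream stratum lookups still match
    lab <- sprintf("%s=%s", spec$strata,
                   as.character(unique(cohort[[spec$strata]]))[1])
    bh$strata <- factor(rep(lab, nrow(bh)))
  }
  beta <- stats::coef(fit)
  if (is.null(beta)) beta <- numeric(0)
  V <- if (length(beta)) stats::vcov(fit)
       else matrix(0, 0, 0)
  if (length(zero_info)) {
    beta <- c(beta, stats::setNames(rep(0, length(zero_info)), zero_info))
    V2 <- matrix(0, length(beta), length(beta),
                 dimnames = list(names(beta), names(beta)))
    if (length(beta) > length(zero_info))
      V2[rownames(V), colnames(V)] <- V
    V <- V2
  }
  structure(list(
    beta = beta,
    cov = V,
    loglik = fit$loglik[length(fit$loglik)],
    n_events = fit$nevent,
    baseline = data.frame(time = bh$time, cumhaz = bh$hazard,
                          strata = bh$strata),
    convergence = list(iterations = fit$iter),
    spec = spec, coxph = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Stratified Cox fit (%s ties, %s timescale): %d events, %d iterations\n",
              x$spec$ties, x$spec$timescale, x$n_events,
              x$convergence$iterations))
  print(hazard_ratios(x))
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals
#'
#' @param fit A `cox_fit`.
#' @param level Confidence level (default 0.95).
#' @param terms Optional coefficient-name pattern to keep.
#' @return Data frame with `term`, `hr`, `lower`, `upper`, `p`.
#' @export
hazard_ratios <- function(fit, level = 0.95, terms = NULL) {
  se <- sqrt(diag(fit$cov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(fit$beta / se)), NA_real_)
  out <- data.frame(term = names(fit$beta),
                    hr = exp(fit$beta),
                    lower = exp(fit$beta - z * se),
                    upper = exp(fit$beta + z * se),
                    p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(terms)) out <- out[grepl(terms, out$term), , drop = FALSE]
  out
}

#' Schoenfeld proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residuals are regressed on event time, giving a
#' score-type chi-square test per covariate and a global test.  Under
#' proportional hazards the per-covariate p-values are approximately
#' uniform, so rejections occur at about the nominal rate.
#'
#' @param fit A `cox_fit` with at least one covariate.
#' @param transform Time transform passed to [survival::cox.zph()]
#'   (default the KM transform, the survival-package default).
#' @return Data frame with `term`, `chisq`, `df`, `p`; the last row is the
#'   global test.
#' @export
schoenfeld_ph_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"))
  if (length(fit$beta) == 0L)
    stop("proportional-hazards test undefined for a model with no covariates")
  z <- survival::cox.zph(fit$coxph, transform = transform, global = TRUE)
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trend test across ordered exposure categories
#'
#' Replaces each participant's exposure with the median of the continuous
#' exposure within their category and refits the Cox model with that
#' single continuous term, returning the Wald p-value for its
#' coefficient.
#'
#' @param cohort A `cohort_table`.
#' @param group_col Name of the category column (e.g. `"fruit_group"`).
#' @param value_col Name of the underlying continuous column (e.g.
#'   `"fruit_g_day"`).
#' @param spec A [cox_model_spec()] supplying the adjustment set (its
#'   `exposure` is ignored).
#' @return List with `p_trend`, `beta`, `se`, `medians`.
#' @export
trend_test <- function(cohort, group_col, value_col, spec) {
  med <- tapply(cohort[[value_col]], cohort[[group_col]], stats::median)
  cohort$.trend <- as.numeric(med[as.character(cohort[[group_col]])])
  sp <- spec; sp$exposure <- ".trend"
  f <- fit_stratified_cox(cohort, sp)
  b <- f$beta[".trend"]; se <- sqrt(f$cov[".trend", ".trend"])
  list(p_trend = unname(2 * stats::pnorm(-abs(b / se))), beta = unname(b),
       se = unname(se), medians = med)
}

#' Age- and sex-adjusted incidence rates by Poisson regression
#'
#' Fits a log-linear model for the event indicator with a log person-years
#' offset, age and sex as covariates and the grouping factor of interest,
#' then predicts each group's rate at the sample-mean age and sex
#' composition, scaled per 1000 person-years.  With no covariates and a
#' single group this reduces exactly to events / person-years.
#'
#' @param cohort A `cohort_table`.
#' @param group_col Name of the grouping column (factor); `NULL` gives the
#'   whole-cohort rate.
#' @param adjust Covariates to adjust for (default age and sex).
#' @param level Confidence level.
#' @return Data frame with `group`, `events`, `person_years`, `rate`
#'   (per 1000 PY), `lower`, `upper`.
#' @export
poisson_adjusted_rates <- function(cohort, group_col = NULL,
                                   adjust = c("age", "sex"), level = 0.95) {
  d <- as.data.frame(cohort)
  # factor adjusters become indicator columns so "sample-mean sex" is the
  # observed composition
  for (v in adjust) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      lev <- levels(factor(d[[v]]))
      for (l in lev[-1]) d[[paste0(v, l)]] <- as.numeric(d[[v]] == l)
      adjust <- c(setdiff(adjust, v), paste0(v, lev[-1]))
    }
  }
  terms <- c(if (!is.null(group_col)) group_col, adjust)
  f <- stats::as.formula(paste("event ~",
                               if (length(terms)) paste(terms, collapse = "+")
                               else "1"))
  g <- stats::glm(f, family = stats::poisson(), data = d,
                  offset = log(d$followup_years))
  groups <- if (is.null(group_col)) "all"
            else levels(factor(d[[group_col]]))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(groups, function(gr) {
    nd <- as.data.frame(lapply(d[, adjust, drop = FALSE], mean))
    if (length(adjust) == 0L) nd <- data.frame(row.names = 1)
    if (!is.null(group_col))
      nd[[group_col]] <- factor(gr, levels = groups)
    X <- stats::model.matrix(stats::delete.response(stats::terms(g)), nd,
                             xlev = g$xlevels)
    eta <- drop(X %*% stats::coef(g))
    se <- sqrt(drop(X %*% stats::vcov(g) %*% t(X)))
    sel <- if (is.null(group_col)) rep(TRUE, nrow(d))
           else d[[group_col]] == gr
    data.frame(group = gr, events = sum(d$event[sel]),
               person_years = sum(d$followup_years[sel]),
               rate = 1000 * exp(eta),
               lower = 1000 * exp(eta - z * se),
               upper = 1000 * exp(eta + z * se),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
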