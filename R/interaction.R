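#' Joint genetic-by-fruit hazard ratio grid
#'
#' A single cohort-stratified, fully-adjusted Cox fit with eight indicator
#' covariates for the 3x3 cells of genetic risk group by fruit intake
#' group; the low-genetic-risk, high-fruit cell is the reference (HR 1).
#'
#' @param cohort A `cohort_table` carrying `genetic_group` and
#'   `fruit_group`.
#' @param spec A [cox_model_spec()] (full tier by default downstream); its
#'   `exposure` field is ignored.
#' @return Data frame of class `joint_effect_grid`: one row per cell with
#'   `genetic_group`, `fruit_group`, `n`, `events`, `hr`, `lower`,
#'   `upper`, plus the `cox_fit` in attribute `fit`.
#' @export
joint_hr_grid <- function(cohort, spec = cox_model_spec(tier = "full")) {
  stopifnot(all(c("genetic_group", "fruit_group") %in% names(cohort)))
  cell <- interaction(cohort$genetic_group, cohort$fruit_group, sep = ":")
  cell <- stats::relevel(factor(cell, ordered = FALSE), ref = "low:high")
  d <- cohort; d$.cell <- cell
  sp <- spec; sp$exposure <- ".cell"
  fit <- fit_stratified_cox(d, sp)
  hrs <- hazard_ratios(fit, terms = "^\\.cell")
  hrs$term <- sub("^\\.cell", "", hrs$term)
  lv <- levels(cell)
  out <- do.call(rbind, lapply(lv, function(l) {
    gg <- strsplit(l, ":")[[1]]
    sel <- cell == l
    if (l == "low:high") {
      hr <- lower <- upper <- 1
    } else {
      i <- match(l, hrs$term)
      hr <- hrs$hr[i]; lower <- hrs$lower[i]; upper <- hrs$upper[i]
    }
    data.frame(genetic_group = gg[1], fruit_group = gg[2],
               n = sum(sel), events = sum(cohort$event[sel]),
               hr = hr, lower = lower, upper = upper,
               stringsAsFactors = FALSE)
  }))
  attr(out, "fit") <- fit
  class(out) <- c("joint_effect_grid", "data.frame")
  out
}

#' Multiplicative genetic-by-fruit interaction
#'
#' Restricts to the four extreme cells (low/high genetic risk crossed with
#' fruit < 200 g/week vs > 100 g/day), fits the fully-adjusted
#' cohort-stratified Cox model with both main effects and their product,
#' and returns the Wald p-value for the product term.
#'
#' @param cohort A `cohort_table` with `genetic_group` and `fruit_group`.
#' @param spec Adjustment specification ([cox_model_spec()], full tier by
#'   default).
#' @return List with `p`, `coef` (product-term log HR), `se`, `n`.
#' @export
multiplicative_interaction <- function(cohort,
                                       spec = cox_model_spec(tier = "full")) {
  d <- cohort[cohort$genetic_group %in% c("low", "high") &
                cohort$fruit_group %in% c("low", "high"), , drop = FALSE]
  d$.ghigh <- as.numeric(d$genetic_group == "high")
  d$.flow <- as.numeric(d$fruit_group == "low")
  d$.prod <- d$.ghigh * d$.flow
  sp <- spec; sp$exposure <- c(".ghigh", ".flow", ".prod")
  fit <- fit_stratified_cox(d, sp)
  b <- fit$beta[".prod"]; se <- sqrt(fit$cov[".prod", ".prod"])
  list(p = unname(2 * stats::pnorm(-abs(b / se))), coef = unname(b),
       se = unname(se), n = nrow(d))
}

#' Additive interaction: RERI and attributable proportion
#'
#' Dichotomizes both exposures -- fruit intake < 200 g/week (exposed) vs
#' >= 200 g/week, and high genetic risk vs low (intermediate participants
#' dropped by default; `genetic_coding = "rest_vs_low"` instead treats
#' quintiles 2-5 as exposed) -- and estimates the three non-reference
#' hazard ratios HR10 (genetic only), HR01 (fruit only) and HR11 (both)
#' from a fully-adjusted stratified Cox model.  Then
#' RERI = HR11 - HR10 - HR01 + 1 and AP = RERI / HR11.  Confidence
#' intervals come from (a) the multivariate delta method on the three log
#' hazard ratios (Hosmer-Lemeshow construction) and (b) a seeded
#' participant-level bootstrap stratified by sub-cohort.
#'
#' @param cohort A `cohort_table` with `genetic_group` and `fruit_group`.
#' @param spec Adjustment specification (full tier by default).
#' @param genetic_coding `"high_vs_low"` (default) or `"rest_vs_low"`.
#' @param n_bootstrap Bootstrap replicates (0 skips the bootstrap CI).
#' @param seed Seed for the bootstrap resampling streams.
#' @param level Confidence level.
#' @return Object of class `additive_interaction` with components
#'   `hr10`, `hr01`, `hr11`, `reri`, `ap`, `reri_ci_delta`, `ap_ci_delta`,
#'   `reri_ci_boot`, `ap_ci_boot`, `p_reri`, `coding`, `n_dropped`.
#' @export
reri_ap <- function(cohort, spec = cox_model_spec(tier = "full"),
                    genetic_coding = c("high_vs_low", "rest_vs_low"),
                    n_bootstrap = 500L, seed = 1L, level = 0.95) {
  genetic_coding <- match.arg(genetic_coding)
  prep <- function(d) {
    if (genetic_coding == "high_vs_low")
      d <- d[d$genetic_group %in% c("low", "high"), , drop = FALSE]
    d$.g <- as.numeric(d$genetic_group != "low")
    d$.f <- as.numeric(d$fruit_group == "low")
    d$.cell <- factor(paste0(d$.g, d$.f), levels = c("00", "10", "01", "11"))
    d
  }
  estimate <- function(d) {
    tab <- table(d$.cell, factor(d$event, levels = 0:1))
    empty <- rownames(tab)[rowSums(tab) == 0 | tab[, "1"] == 0]
    if (length(empty))
      stop("additive interaction non-estimable: no events in cell(s) ",
           paste(empty, collapse = ", "))
    sp <- spec; sp$exposure <- ".cell"
    fit <- fit_stratified_cox(d, sp)
    cn <- paste0(".cell", c("10", "01", "11"))
    b <- fit$beta[cn]
    V <- fit$cov[cn, cn]
    hr <- exp(b)
    reri <- hr[3] - hr[1] - hr[2] + 1
    ap <- reri / hr[3]
    g_reri <- c(-hr[1], -hr[2], hr[3])
    g_ap <- c(-hr[1] / hr[3], -hr[2] / hr[3], (hr[1] + hr[2] - 1) / hr[3])
    list(hr = unname(hr), reri = unname(reri), ap = unname(ap),
         se_reri = sqrt(drop(t(g_reri) %*% V %*% g_reri)),
         se_ap = sqrt(drop(t(g_ap) %*% V %*% g_ap)))
  }
  d0 <- prep(cohort)
  est <- estimate(d0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  boot_reri <- boot_ap <- NULL
  if (n_bootstrap > 0) {
    bs <- bootstrap_estimates(
      d0, n_bootstrap, seed,
      function(d) { e <- estimate(d); c(e$reri, e$ap) })
    boot_reri <- stats::quantile(bs[, 1], c((1 - level) / 2, 1 - (1 - level) / 2),
                                 names = FALSE)
    boot_ap <- stats::quantile(bs[, 2], c((1 - level) / 2, 1 - (1 - level) / 2),
                               names = FALSE)
  }
  structure(list(
    hr10 = est$hr[1], hr01 = est$hr[2], hr11 = est$hr[3],
    reri = est$reri, ap = est$ap,
    reri_ci_delta = c(est$reri - z * est$se_reri, est$reri + z * est$se_reri),
    ap_ci_delta = c(est$ap - z * est$se_ap, est$ap + z * est$se_ap),
    reri_ci_boot = boot_reri, ap_ci_boot = boot_ap,
    p_reri = 2 * stats::pnorm(-abs(est$reri / est$se_reri)),
    coding = list(genetic = genetic_coding,
                  fruit = "low (<200 g/week) vs >=200 g/week"),
    n_used = nrow(d0), n_dropped = nrow(cohort) - nrow(d0)),
    class = "additive_interaction")
}

#' @export
print.additive_interaction <- function(x, ...) {
  cat(sprintf("Additive interaction (%s genetic coding)\n", x$coding$genetic))
  cat(sprintf("  HR10 %.3f, HR01 %.3f, HR11 %.3f\n", x$hr10, x$hr01, x$hr11))
  cat(sprintf("  RERI %.3f (delta %.3f to %.3f)", x$reri,
              x$reri_ci_delta[1], x$reri_ci_delta[2]))
  if (!is.null(x$reri_ci_boot))
    cat(sprintf(" (bootstrap %.3f to %.3f)", x$reri_ci_boot[1],
                x$reri_ci_boot[2]))
  cat(sprintf("\n  AP %.3f (delta %.3f to %.3f)\n", x$ap,
              x$ap_ci_delta[1], x$ap_ci_delta[2]))
  invisible(x)
}

# Seeded participant-level bootstrap stratified by sub-cohort.  Per-replicate
# seeds are drawn once from the master seed (stream splitting), so replicate
# k is reproducible regardless of how many replicates run.
bootstrap_estimates <- function(cohort, B, seed, fun, max_drop = 0.05) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  idx_by_str <- split(seq_len(nrow(cohort)), cohort$subcohort)
  out <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- unlist(lapply(idx_by_str, function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]), use.names = FALSE)
    val <- tryCatch(fun(cohort[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val)) dropped <- dropped + 1L else out[[b]] <- val
  }
  if (dropped > max_drop * B)
    stop(sprintf("bootstrap failed: %d of %d replicates did not converge",
                 dropped, B))
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Per-SNP additive interaction scan with fruit intake
#'
#' For every SNP in the panel, fits an adjusted cohort-stratified Cox model
#' with the per-allele risk count, the dichotomized fruit exposure
#' (< 200 g/week vs not) and their product, computes the per-allele RERI
#' `exp(bg+bf+bgf) - exp(bg) - exp(bf) + 1`, its delta-method standard
#' error and p-value, and flags SNPs passing the Bonferroni threshold
#' 0.05 / n_snps.
#'
#' @param cohort A `cohort_table` with `fruit_group`.
#' @param genotypes 0/1/2 matrix aligned with `cohort` rows.
#' @param panel Matching [snp_panel()].
#' @param spec Adjustment specification; defaults to the base genetic
#'   model (age and sex).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame: `snp_id`, `reri`, `se`, `p`, `bonferroni_sig`, with
#'   the threshold in attribute `threshold`.
#' @export
snp_by_fruit_scan <- function(cohort, genotypes, panel,
                              spec = cox_model_spec(tier = "base",
                                                    analysis = "genetic"),
                              alpha = 0.05) {
  stopifnot(nrow(genotypes) == nrow(cohort))
  d <- as.data.frame(cohort)
  d$.f <- as.numeric(d$fruit_group == "low")
  thr <- alpha / nrow(panel)
  res <- lapply(seq_len(nrow(panel)), function(j) {
    d$.g <- genotypes[, panel$snp_id[j]]
    out <- tryCatch({
      sp <- spec; sp$exposure <- c(".g", ".f", ".gf")
      d$.gf <- d$.g * d$.f
      fit <- fit_stratified_cox(d, sp)
      cn <- c(".g", ".f", ".gf")
      b <- fit$beta[cn]; V <- fit$cov[cn, cn]
      h10 <- exp(b[1]); h01 <- exp(b[2]); h11 <- exp(sum(b))
      reri <- h11 - h10 - h01 + 1
      grad <- c(h11 - h10, h11 - h01, h11)
      se <- sqrt(drop(t(grad) %*% V %*% grad))
      c(reri, se, 2 * stats::pnorm(-abs(reri / se)))
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    out
  })
  res <- do.call(rbind, res)
  out <- data.frame(snp_id = panel$snp_id, reri = res[, 1], se = res[, 2],
                    p = res[, 3],
                    bonferroni_sig = !is.na(res[, 3]) & res[, 3] < thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}
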