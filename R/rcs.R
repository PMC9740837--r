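#' Restricted cubic spline basis
#'
#' Truncated-power parameterisation with linear tails.  With knots
#' t1 < t2 < t3 the basis has two columns: the identity and one nonlinear
#' term
#' \deqn{[(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2)
#'        + (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)] / (t_3-t_1)^2,}
#' which is continuous with continuous first and second derivatives and
#' linear outside the boundary knots.  More knots add one nonlinear column
#' per interior knot in the same construction.
#'
#' @param x Numeric vector.
#' @param knots Increasing numeric vector of at least 3 knots.
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- sort(knots)
  if (length(k) < 3L) stop("need at least 3 knots")
  K <- length(k)
  pos3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(K - 2L), function(j) {
    (pos3(x - k[j]) -
       pos3(x - k[K - 1L]) * (k[K] - k[j]) / (k[K] - k[K - 1L]) +
       pos3(x - k[K]) * (k[K - 1L] - k[j]) / (k[K] - k[K - 1L])) /
      (k[K] - k[1L])^2
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("lin", paste0("nl", seq_len(K - 2L)))
  out
}

#' Spline dose-response curve for a continuous exposure
#'
#' Models the exposure with a restricted cubic spline (three knots at the
#' 25th, 50th and 75th percentiles by default) inside an adjusted,
#' cohort-stratified Cox model.  The hazard-ratio curve is expressed
#' relative to the 50th percentile (the curve equals 1 there).  The
#' overall association is a Wald test on all spline coefficients; the
#' departure from log-linearity is a Wald test on the nonlinear
#' coefficient(s).
#'
#' @param cohort A `cohort_table`.
#' @param exposure Name of the continuous exposure column.
#' @param spec A [cox_model_spec()] supplying the adjustment set (its
#'   `exposure` field is ignored).
#' @param knot_probs Percentiles defining the knots.
#' @param ref_prob Percentile of the reference value (default the median).
#' @param grid_n Number of curve evaluation points between the 1st and
#'   99th exposure percentiles.
#' @return List of class `rcs_dose_response`: `p_overall`, `p_nonlinear`,
#'   `knots`, `ref`, `curve` (data frame: exposure, hr, lower, upper) and
#'   the underlying `cox_fit`.
#' @export
rcs_dose_response <- function(cohort, exposure, spec,
                              knot_probs = c(0.25, 0.50, 0.75),
                              ref_prob = 0.50, grid_n = 100L) {
  x <- cohort[[exposure]]
  knots <- unique(stats::quantile(x, knot_probs, names = FALSE))
  if (length(knots) < 3L)
    stop("degenerate exposure: knots at the stated percentiles coincide")
  B <- rcs_basis(x, knots)
  d <- cohort
  cn <- paste0(".rcs_", colnames(B))
  d[cn] <- as.data.frame(B)
  sp <- spec; sp$exposure <- cn
  fit <- fit_stratified_cox(d, sp)
  bs <- fit$beta[cn]
  Vs <- fit$cov[cn, cn, drop = FALSE]
  wald <- function(idx) {
    b <- bs[idx]; V <- Vs[idx, idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(V) %*% b)
    stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
  }
  ref <- stats::quantile(x, ref_prob, names = FALSE)
  grid <- seq(stats::quantile(x, 0.01), stats::quantile(x, 0.99),
              length.out = grid_n)
  D <- rcs_basis(grid, knots) -
    matrix(rcs_basis(ref, knots), grid_n, length(bs), byrow = TRUE)
  loghr <- drop(D %*% bs)
  se <- sqrt(rowSums((D %*% Vs) * D))
  structure(list(
    p_overall = wald(seq_along(bs)),
    p_nonlinear = wald(seq_along(bs)[-1]),
    knots = knots, ref = ref,
    curve = data.frame(exposure = grid, hr = exp(loghr),
                       lower = exp(loghr - 1.96 * se),
                       upper = exp(loghr + 1.96 * se)),
    fit = fit), class = "rcs_dose_response")
}

#' @export
print.rcs_dose_response <- function(x, ...) {
  cat(sprintf("Restricted cubic spline dose-response (knots %s; reference %.4g)\n",
              paste(signif(x$knots, 4), collapse = ", "), x$ref))
  cat(sprintf("  p overall = %.3g, p nonlinear = %.3g\n",
              x$p_overall, x$p_nonlinear))
  invisible(x)
}
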