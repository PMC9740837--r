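#' Compute the weighted polygenic risk score
#'
#' For each participant the score is the sum over panel SNPs of the
#' risk-allele count multiplied by the SNP's weight coefficient.  Scores
#' are also standardized (z-scored) on the scoring sample, and participants
#' are grouped into low (lowest quintile), intermediate (quintiles 2--4)
#' and high (highest quintile) genetic risk.
#'
#' Missing genotype calls are rejected rather than imputed, and every panel
#' SNP must be present in the genotype matrix; columns are matched by SNP id
#' so column order is irrelevant.
#'
#' @param genotypes Matrix of 0/1/2 risk-allele counts, columns named by
#'   SNP id, rows optionally named by participant id.
#' @param panel A [snp_panel()] with the weights.
#' @return A data frame of class `prs_result` with `participant_id`,
#'   `prs_raw`, `prs_std` and `genetic_group`.
#' @export
compute_prs <- function(genotypes, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.null(colnames(genotypes)))
    stop("genotype matrix must have SNP ids as column names")
  missing_ids <- setdiff(panel$snp_id, colnames(genotypes))
  if (length(missing_ids))
    stop("panel SNPs absent from the genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) sprintf(" (and %d more)",
                                              length(missing_ids) - 5))
  g <- genotypes[, panel$snp_id, drop = FALSE]
  if (anyNA(g))
    stop("missing genotype calls are not allowed (no silent imputation); ",
         sum(is.na(g)), " missing values found")
  if (!all(g %in% 0:2)) stop("genotypes must be 0/1/2 risk-allele counts")
  prs_raw <- as.numeric(g %*% panel$weight)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  s <- stats::sd(prs_raw)
  structure(data.frame(
    participant_id = ids,
    prs_raw = prs_raw,
    prs_std = if (s > 0) (prs_raw - mean(prs_raw)) / s else prs_raw * 0,
    genetic_group = assign_genetic_groups(prs_raw),
    stringsAsFactors = FALSE),
    class = c("prs_result", "data.frame"))
}

#' Assign quintile-based genetic risk groups
#'
#' Boundaries are the empirical 20th and 80th percentiles of the scores
#' (type-7 quantiles).  Values strictly below the 20th percentile are
#' `low`, strictly above the 80th are `high`, everything else is
#' `intermediate`.  The rule is deterministic under ties: a score equal to
#' the 80th percentile stays `intermediate` (never promoted to `high`), and
#' one equal to the 20th percentile is `intermediate` (only strictly
#' smaller scores are `low`).  The assignment depends only on ranks, so any
#' strictly monotone transform of the scores gives identical groups.
#'
#' @param prs Numeric vector of scores with at least 5 distinct values.
#' @return Factor with levels `low`, `intermediate`, `high` (low is the reference).
#' @export
assign_genetic_groups <- function(prs) {
  if (any(!is.finite(prs))) stop("scores must be finite")
  if (length(unique(prs)) < 5L)
    stop("quintile groups undefined: fewer than 5 distinct score values")
  q <- stats::quantile(prs, c(0.2, 0.8), names = FALSE)
  grp <- ifelse(prs < q[1], "low", ifelse(prs > q[2], "high", "intermediate"))
  # plain factor (low as reference) so model indicators contrast against low
  factor(grp, levels = c("low", "intermediate", "high"))
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("Polygenic risk scores for %d participants\n", nrow(x)))
  cat(sprintf("  raw score: mean %.4g, sd %.4g\n", mean(x$prs_raw),
              stats::sd(x$prs_raw)))
  print(table(x$genetic_group))
  invisible(x)
}

#' @rdname compute_prs
#' @param prs A `prs_result`.
#' @param path Output path for the delimited export.
#' @export
write_prs_result <- function(prs, path) {
  utils::write.csv(as.data.frame(prs), path, row.names = FALSE)
  invisible(path)
}
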