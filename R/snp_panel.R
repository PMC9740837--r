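#' SNP weight panels
#'
#' A `snp_panel` records, for each variant in the risk score, its identifier,
#' risk allele, risk-allele frequency and weight coefficient.  Weights are
#' inputs to the score (derived externally, e.g. by GWAS meta-analysis); the
#' generator can also draw a synthetic panel.
#'
#' @param snp_id Character vector of unique variant identifiers.
#' @param risk_allele Character vector of risk alleles (A/C/G/T).
#' @param allele_freq Risk-allele frequencies in (0, 1).
#' @param weight Per-allele weight coefficients.
#' @return A data frame of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, risk_allele, allele_freq, weight) {
  n <- length(snp_id)
  if (length(risk_allele) != n || length(allele_freq) != n ||
      length(weight) != n)
    stop("snp_panel fields must have equal lengths")
  if (anyDuplicated(snp_id)) stop("duplicate snp_id in panel")
  if (any(!is.finite(allele_freq)))
    stop("non-finite allele frequency in panel")
  if (any(allele_freq <= 0 | allele_freq >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (any(!is.finite(weight))) stop("non-finite weight in panel")
  structure(data.frame(snp_id = as.character(snp_id),
                       risk_allele = as.character(risk_allele),
                       allele_freq = allele_freq,
                       weight = weight,
                       stringsAsFactors = FALSE),
            class = c("snp_panel", "data.frame"))
}

#' Draw a synthetic SNP panel
#'
#' Frequencies are uniform on `allele_freq_range`; weights are half-normal
#' with spread `weight_sd` (risk alleles carry non-negative weights, so the
#' score accumulates risk).
#'
#' @param cfg A [generator_config()].
#' @return A [snp_panel()] with `cfg$n_snps` rows.
#' @export
generate_snp_panel <- function(cfg) {
  validate_generator_config(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_snps
  snp_panel(
    snp_id = sprintf("rs%07d", sample.int(9999999L, m)),
    risk_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    allele_freq = stats::runif(m, cfg$allele_freq_range[1],
                               cfg$allele_freq_range[2]),
    weight = abs(stats::rnorm(m, 0, cfg$weight_sd)))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each SNP is drawn independently under Hardy-Weinberg equilibrium: the
#' risk-allele count is Binomial(2, p), giving genotype probabilities
#' ((1-p)^2, 2p(1-p), p^2).  No linkage disequilibrium or genotyping error
#' is modelled.
#'
#' @param cfg A [generator_config()]; its seed (offset for the genotype
#'   stream) determines the matrix.
#' @param panel A [snp_panel()] supplying the frequencies.
#' @return Integer matrix (`n_participants` x `nrow(panel)`) of 0/1/2
#'   risk-allele counts, columns named by `snp_id`.
#' @export
generate_genotypes <- function(cfg, panel) {
  validate_generator_config(cfg)
  stopifnot(inherits(panel, "snp_panel"))
  p <- panel$allele_freq
  if (any(!is.finite(p))) stop("non-finite allele frequency")
  n <- cfg$n_participants
  m <- nrow(panel)
  set.seed(cfg$seed + 1L)
  g <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  colnames(g) <- panel$snp_id
  storage.mode(g) <- "integer"
  g
}

#' Read/write panel and genotype files
#'
#' The panel is 4-column delimited text; genotypes are a delimited matrix
#' keyed by `participant_id` in the first column.
#'
#' @param panel A [snp_panel()]; `genotypes` an integer matrix with
#'   participant ids as rownames (or NULL for 1..n).
#' @param path Output file path.
#' @return Readers return the restored object; writers return `path`.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_snp_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_snp_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  snp_panel(d$snp_id, d$risk_allele, d$allele_freq, d$weight)
}

#' @rdname panel_io
#' @export
write_genotypes <- function(genotypes, path) {
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- seq_len(nrow(genotypes))
  d <- data.frame(participant_id = ids, genotypes, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_genotypes <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  g <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- d$participant_id
  g
}

#' Export genotypes as a minimal VCFv4.2 file
#'
#' Writes a GT-only VCF (one pseudo-locus per SNP on a synthetic contig) so
#' downstream tools that expect VCF input can consume the simulated panel.
#' The risk allele is written as ALT, so the ALT dosage equals the
#' risk-allele count.
#'
#' @param genotypes 0/1/2 matrix from [generate_genotypes()].
#' @param panel Matching [snp_panel()].
#' @param path Output `.vcf` path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, panel, path) {
  stopifnot(ncol(genotypes) == nrow(panel))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("P%06d", seq_len(nrow(genotypes)))
  gt_code <- c("0/0", "0/1", "1/1")
  other <- c(A = "G", C = "T", G = "A", T = "C")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=SYN1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(nrow(panel))) {
    row <- paste(c("SYN1", j, panel$snp_id[j],
                   other[[panel$risk_allele[j]]], panel$risk_allele[j],
                   ".", "PASS", "GT", gt_code[genotypes[, j] + 1L]),
                 collapse = "\t")
    writeLines(row, con)
  }
  invisible(path)
}
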