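#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expects the ten-column layout SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N
#' (header required, tab-separated, '.' for missing).
#'
#' @param path file path.
#' @param trait_id,cohort_id labels attached to the result.
#' @return `summary_stats` data.frame.
#' @export
read_sumstats <- function(path, trait_id = NULL, cohort_id = NULL) {
  x <- utils::read.delim(path, na.strings = ".", colClasses = list(
    CHR = "character"), stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  miss <- setdiff(need, colnames(x))
  if (length(miss)) stop_arg("missing column(s): %s", paste(miss, collapse = ", "))
  x <- x[, need]
  attr(x, "trait_id") <- trait_id
  attr(x, "cohort_id") <- cohort_id
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Write summary statistics as tab-delimited text
#'
#' @param stats `summary_stats` data.frame.
#' @param path destination.
#' @export
write_sumstats <- function(stats, path) {
  cols <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  utils::write.table(as.data.frame(stats)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Write a cohort's genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT calls obtained by rounding dosages to
#' 0/1/2 (0/0, 0/1, 1/1 with the effect allele as ALT). Intended for
#' interoperability with standard variant tooling, not as a lossless dosage
#' container; use [write_dosages()] for exact dosages.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param path destination (.vcf).
#' @export
write_vcf <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=glycoloc synthetic cohort",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  ids <- sprintf("S%04d", seq_len(nrow(cohort$dosages)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt_map <- c("0/0", "0/1", "1/1")
  g <- pmin(pmax(round(cohort$dosages), 0), 2)
  for (j in seq_len(ncol(g))) {
    row <- c(cohort$snp$CHR[j], cohort$snp$POS[j], cohort$snp$SNP[j],
             cohort$snp$OA[j], cohort$snp$EA[j], ".", "PASS", ".", "GT",
             gt_map[g[, j] + 1])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a cohort's dosage matrix as TSV
#'
#' Columns: SNP, CHR, POS, EA, OA then one column per sample.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param path destination.
#' @export
write_dosages <- function(cohort, path) {
  ids <- sprintf("S%04d", seq_len(nrow(cohort$dosages)))
  out <- cbind(cohort$snp, as.data.frame(t(cohort$dosages)))
  colnames(out) <- c(colnames(cohort$snp), ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phenotypes and covariates as TSV
#'
#' Header `sample_id, age, sex, <trait...>`.
#'
#' @param cohort a cohort with covariates.
#' @param phenotypes samples x traits matrix.
#' @param path destination.
#' @export
write_phenotypes <- function(cohort, phenotypes, path) {
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(nrow(phenotypes))),
                    age = cohort$covariates$age, sex = cohort$covariates$sex,
                    phenotypes, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a scenario as JSON
#'
#' @param scenario a [sim_scenario()].
#' @param path destination (.json).
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Regional association plot
#'
#' Base-graphics scatter of -log10(p) against position, highlighting the
#' sentinel; optionally overlays per-SNP natural-log approximate Bayes
#' factors from a colocalisation run on a secondary axis.
#'
#' @param stats `summary_stats` for one region.
#' @param sentinel optional SNP id to highlight.
#' @param coloc optional `coloc_res` whose lnABFs to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot_region <- function(stats, sentinel = NULL, coloc = NULL, ...) {
  ok <- !is.na(stats$P)
  graphics::plot(stats$POS[ok] / 1e6, -log10(stats$P[ok]),
                 xlab = sprintf("position on chr %s (Mb)", stats$CHR[1]),
                 ylab = expression(-log[10](p)), pch = 20,
                 col = "grey40", ...)
  if (!is.null(sentinel)) {
    i <- match(sentinel, stats$SNP)
    graphics::points(stats$POS[i] / 1e6, -log10(stats$P[i]),
                     pch = 18, col = "purple", cex = 1.6)
  }
  if (!is.null(coloc)) {
    i <- match(coloc$lnabf$SNP, stats$SNP)
    l <- coloc$lnabf$lABF1
    sc <- max(-log10(stats$P[ok])) / max(abs(l) + 1e-9)
    graphics::points(stats$POS[i] / 1e6, pmax(l, 0) * sc, pch = 4,
                     col = "steelblue")
    graphics::legend("topright", legend = c("-log10 p", "ln ABF (scaled)"),
                     pch = c(20, 4), col = c("grey40", "steelblue"),
                     bty = "n")
  }
  invisible(NULL)
}
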