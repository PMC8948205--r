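#' Harmonise two cohorts' summary statistics on SNP id and alleles
#'
#' Matches records by SNP id and harmonises cohort B to cohort A's effect
#' allele: identical (EA, OA) pairs pass through; swapped pairs have BETA
#' negated and EAF reflected; any other pair is unresolvable and reported
#' with reason "allele_mismatch". SNPs absent from either cohort are logged
#' as "missing_in_A"/"missing_in_B".
#'
#' @param statsA,statsB `summary_stats` data.frames.
#' @return list `a`, `b` (aligned, harmonised, same SNP order) and `removed`
#'   (SNP, reason).
#' @export
harmonise_pair <- function(statsA, statsB) {
  removed <- data.frame(SNP = character(), reason = character())
  common <- intersect(statsA$SNP, statsB$SNP)
  onlyA <- setdiff(statsA$SNP, common)
  onlyB <- setdiff(statsB$SNP, common)
  if (length(onlyA)) removed <- rbind(removed,
    data.frame(SNP = onlyA, reason = "missing_in_B"))
  if (length(onlyB)) removed <- rbind(removed,
    data.frame(SNP = onlyB, reason = "missing_in_A"))
  a <- statsA[match(common, statsA$SNP), , drop = FALSE]
  b <- statsB[match(common, statsB$SNP), , drop = FALSE]
  same <- a$EA == b$EA & a$OA == b$OA
  swap <- a$EA == b$OA & a$OA == b$EA
  bad  <- !(same | swap)
  if (any(swap)) {
    b$BETA[swap] <- -b$BETA[swap]
    b$EAF[swap] <- 1 - b$EAF[swap]
    tmp <- b$EA[swap]; b$EA[swap] <- b$OA[swap]; b$OA[swap] <- tmp
  }
  if (any(bad)) removed <- rbind(removed,
    data.frame(SNP = a$SNP[bad], reason = "allele_mismatch"))
  keep <- !bad
  list(a = a[keep, , drop = FALSE], b = b[keep, , drop = FALSE],
       removed = removed)
}

#' Cross-cohort QC before meta-analysis
#'
#' After allele harmonisation, removes SNPs whose effect-allele frequencies
#' differ between the cohorts by more than `eaf_diff` in absolute value, and
#' SNPs whose minor allele count `2 * N * min(EAF, 1 - EAF)` is at or below
#' `max_mac` in either cohort. Removal decisions are symmetric in cohort
#' order and each removal is logged with its reason.
#'
#' @param statsA,statsB `summary_stats` data.frames (one trait each).
#' @param eaf_diff allele-frequency difference threshold (strict; default
#'   0.3).
#' @param max_mac minor-allele-count threshold: MAC <= `max_mac` is removed
#'   (default 6).
#' @return list `a`, `b` (filtered, harmonised) and `removed` (SNP, reason
#'   in {allele_mismatch, missing_in_*, eaf_diff, low_mac_A, low_mac_B}).
#' @export
qc_filter <- function(statsA, statsB, eaf_diff = 0.3, max_mac = 6) {
  h <- harmonise_pair(statsA, statsB)
  a <- h$a; b <- h$b; removed <- h$removed
  drop_eaf <- abs(a$EAF - b$EAF) > eaf_diff
  mac_a <- 2 * a$N * pmin(a$EAF, 1 - a$EAF)
  mac_b <- 2 * b$N * pmin(b$EAF, 1 - b$EAF)
  drop_mac_a <- !drop_eaf & mac_a <= max_mac
  drop_mac_b <- !drop_eaf & !drop_mac_a & mac_b <= max_mac
  log_add <- function(snps, reason) if (length(snps))
    data.frame(SNP = snps, reason = reason) else NULL
  removed <- rbind(removed,
                   log_add(a$SNP[drop_eaf], "eaf_diff"),
                   log_add(a$SNP[drop_mac_a], "low_mac_A"),
                   log_add(a$SNP[drop_mac_b], "low_mac_B"))
  keep <- !(drop_eaf | drop_mac_a | drop_mac_b)
  list(a = a[keep, , drop = FALSE], b = b[keep, , drop = FALSE],
       removed = removed)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-SNP effects across cohorts with weights `1/SE^2`:
#' `beta = sum(w_i b_i)/sum(w_i)`, `se = 1/sqrt(sum(w_i))`, two-sided Wald
#' p-value, `N = sum(n_i)` and N-weighted effect-allele frequency. Inputs
#' must already be harmonised (e.g. via [qc_filter()]); SNPs present in
#' fewer than two cohorts are dropped and logged.
#'
#' @param stats list of harmonised `summary_stats` data.frames.
#' @param trait_id label for the combined result.
#' @return object of class `meta_result`: a `summary_stats` data.frame with
#'   attributes `lambda_gc` (NA until [genomic_control()] is applied) and
#'   `dropped` (SNPs in < 2 cohorts).
#' @export
ivw_meta <- function(stats, trait_id = attr(stats[[1]], "trait_id") %||% "trait") {
  if (length(stats) < 2) stop_arg("need >= 2 cohorts")
  all_ids <- unique(unlist(lapply(stats, `[[`, "SNP")))
  count <- rowSums(matrix(vapply(stats, function(s) all_ids %in% s$SNP,
                                 logical(length(all_ids))),
                          nrow = length(all_ids)))
  keep_ids <- all_ids[count >= 2]
  dropped <- all_ids[count < 2]
  tmpl <- stats[[1]][match(keep_ids, stats[[1]]$SNP), , drop = FALSE]
  for (s in stats[-1]) {            # fill metadata for SNPs absent from cohort 1
    miss <- is.na(tmpl$SNP)
    if (!any(miss)) break
    j <- match(keep_ids[miss], s$SNP)
    tmpl[miss, ][!is.na(j), ] <- s[j[!is.na(j)], , drop = FALSE]
  }
  sw <- swb <- nn <- eafn <- rep(0, length(keep_ids))
  for (s in stats) {
    i <- match(keep_ids, s$SNP)
    ok <- !is.na(i)
    if (any(s$SE[i[ok]] <= 0, na.rm = TRUE))
      stop_arg("non-positive SE in input summary statistics")
    w <- 1 / s$SE[i[ok]]^2
    sw[ok] <- sw[ok] + w
    swb[ok] <- swb[ok] + w * s$BETA[i[ok]]
    nn[ok] <- nn[ok] + s$N[i[ok]]
    eafn[ok] <- eafn[ok] + s$N[i[ok]] * s$EAF[i[ok]]
  }
  beta <- swb / sw
  se <- 1 / sqrt(sw)
  out <- data.frame(
    SNP = keep_ids, CHR = tmpl$CHR, POS = tmpl$POS,
    EA = tmpl$EA, OA = tmpl$OA,
    EAF = eafn / nn, BETA = beta, SE = se, P = wald_p(beta / se),
    N = nn, stringsAsFactors = FALSE)
  attr(out, "trait_id") <- trait_id
  attr(out, "cohort_id") <- "meta"
  attr(out, "lambda_gc") <- NA_real_
  attr(out, "dropped") <- dropped
  class(out) <- c("meta_result", "summary_stats", "data.frame")
  out
}

#' Genomic-control correction of meta-analysis statistics
#'
#' Estimates the inflation factor `lambda = median(z^2) / 0.4549364` (the
#' median of a 1-df chi-square). When `lambda > 1` every SE is inflated by
#' `sqrt(lambda)` and p-values recomputed; when `lambda <= 1` statistics are
#' left unchanged (no deflation, the convention of standard meta-analysis
#' tools). Lambda is recorded either way.
#'
#' @param meta a `meta_result` (>= 100 SNPs for a stable median).
#' @return the corrected `meta_result` with attribute `lambda_gc` set.
#' @export
genomic_control <- function(meta) {
  ok <- !is.na(meta$BETA) & !is.na(meta$SE)
  if (sum(ok) < 100) stop_arg("need >= 100 SNPs for a stable median")
  z2 <- (meta$BETA[ok] / meta$SE[ok])^2
  lambda <- stats::median(z2) / stats::qchisq(0.5, 1)
  if (lambda > 1) {
    meta$SE <- meta$SE * sqrt(lambda)
    meta$P <- ifelse(is.na(meta$BETA), NA_real_, wald_p(meta$BETA / meta$SE))
  }
  attr(meta, "lambda_gc") <- lambda
  meta
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW meta-analysis, trait '%s': %d SNPs, N = %s\n",
              attr(x, "trait_id") %||% "?", nrow(x),
              paste(unique(stats::na.omit(x$N)), collapse = "/")))
  lg <- attr(x, "lambda_gc")
  cat(sprintf("  lambda_GC = %s; min p = %.3g\n",
              if (is.na(lg)) "not estimated" else sprintf("%.4f", lg),
              suppressWarnings(min(x$P, na.rm = TRUE))))
  invisible(x)
}

#' Bonferroni significance threshold across a trait panel
#'
#' @param alpha base genome-wide level (default 5e-8).
#' @param n_traits number of traits tested.
#' @return list with `threshold` (full precision) and `threshold_3sf`
#'   (rounded to 3 significant figures for reporting).
#' @export
significance_threshold <- function(alpha = 5e-8, n_traits = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must lie in (0,1)")
  if (n_traits < 1) stop_arg("n_traits must be >= 1")
  thr <- alpha / n_traits
  list(threshold = thr, threshold_3sf = signif(thr, 3))
}
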