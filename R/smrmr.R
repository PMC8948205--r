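#' SMR test at one instrument
#'
#' Wald-ratio test linking an exposure (e.g. a molecular trait) to an
#' outcome through a single SNP: the ratio estimate is
#' `b_smr = beta_y / beta_x` and the test statistic
#' `T_SMR = z_x^2 * z_y^2 / (z_x^2 + z_y^2)` is compared to a 1-df
#' chi-square. T_SMR tends to `z_y^2` as the exposure association becomes
#' exact, and is 0 when the outcome shows no association.
#'
#' @param beta_x,se_x exposure effect and SE at the instrument.
#' @param beta_y,se_y outcome effect and SE at the instrument.
#' @return list `b_smr`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(beta_x, se_x, beta_y, se_y) {
  zx <- beta_x / se_x
  if (any(zx == 0)) stop_arg("z_x = 0: ratio estimate undefined")
  zy <- beta_y / se_y
  t <- zx^2 * zy^2 / (zx^2 + zy^2)
  list(b_smr = beta_y / beta_x, t_smr = t,
       p_smr = stats::pchisq(t, 1, lower.tail = FALSE))
}

#' Instrument selection for the HEIDI test
#'
#' Builds the eligible SNP set around a sentinel and partitions it into
#' 'target' and 'rejected' sets. Eligibility: (1) within `window` bp of the
#' sentinel; (2) present in both datasets; (3) MAF at or above `maf_min` in
#' both; (4) squared z in the primary (exposure) GWAS at or above `z2_min`.
#' The top SNP is the eligible SNP with the lowest primary-GWAS p-value
#' among those with r-squared above `r2_top` to the sentinel; it seeds the
#' target set. Remaining eligible SNPs are visited in ascending SMR p-value:
#' a SNP with r-squared above `r2_reject` to any target SNP is rejected,
#' otherwise added, stopping once the target set holds `cap` SNPs. Ties are
#' broken by SNP id, so selection is deterministic.
#'
#' @param sumstats_x exposure (primary) `summary_stats`.
#' @param sumstats_y outcome `summary_stats`.
#' @param sentinel sentinel SNP id.
#' @param ldref an [ld_reference()].
#' @param window,maf_min,z2_min,r2_top,r2_reject,cap selection parameters
#'   (defaults 250 kb, 0.03, 10, 0.8, 0.9, 20).
#' @return list `top_snp`, `target`, `rejected`, `eligible`, `status`
#'   ("ok" or "heidi_skipped_lt3" when fewer than 3 target SNPs).
#' @export
heidi_select <- function(sumstats_x, sumstats_y, sentinel, ldref,
                         window = 250000, maf_min = 0.03, z2_min = 10,
                         r2_top = 0.8, r2_reject = 0.9, cap = 20L) {
  x <- harmonise_to_ref(sumstats_x, ldref)
  y <- harmonise_to_ref(sumstats_y, ldref)
  common <- intersect(x$SNP, y$SNP)
  x <- x[match(common, x$SNP), , drop = FALSE]
  y <- y[match(common, y$SNP), , drop = FALSE]
  spos <- ldref$snp$POS[match(sentinel, ldref$snp$SNP)]
  schr <- ldref$snp$CHR[match(sentinel, ldref$snp$SNP)]
  if (is.na(spos)) stop_arg("sentinel '%s' not in the reference panel", sentinel)
  maf_x <- pmin(x$EAF, 1 - x$EAF)
  maf_y <- pmin(y$EAF, 1 - y$EAF)
  elig <- x$CHR == schr & abs(x$POS - spos) <= window &
    maf_x >= maf_min & maf_y >= maf_min &
    !is.na(x$BETA) & !is.na(y$BETA) &
    (x$BETA / x$SE)^2 >= z2_min
  ex <- x[elig, , drop = FALSE]
  ey <- y[elig, , drop = FALSE]
  if (!nrow(ex)) stop_arg("no_instrument: no eligible SNP near '%s'", sentinel)
  r2_sent <- as.numeric(ld_cor(ldref, ex$SNP, sentinel)^2)
  near <- r2_sent > r2_top
  if (!any(near)) stop_arg("no_instrument: no eligible SNP with r2 > %.2f to '%s'",
                           r2_top, sentinel)
  o <- order(ex$P, ex$SNP)
  top <- ex$SNP[o[near[o]][1]]
  smr_p <- vapply(seq_len(nrow(ex)), function(i)
    smr_test(ex$BETA[i], ex$SE[i], ey$BETA[i], ey$SE[i])$p_smr, 0)
  target <- top
  rejected <- character()
  queue <- ex$SNP[order(smr_p, ex$SNP)]
  queue <- setdiff(queue, top)
  for (s in queue) {
    if (length(target) >= cap) break
    r2 <- as.numeric(ld_cor(ldref, s, target)^2)
    if (any(r2 > r2_reject)) rejected <- c(rejected, s)
    else target <- c(target, s)
  }
  list(top_snp = top, target = target, rejected = rejected,
       eligible = ex$SNP,
       status = if (length(target) < 3) "heidi_skipped_lt3" else "ok")
}

# delta-method variance of b_smr_i = beta_y_i / beta_x_i and covariance
# between instruments i and j, with LD-driven covariance of the per-SNP
# effect estimates: cov(beta_i, beta_j) ~ r_ij * se_i * se_j within each
# trait, independent traits.
smr_ratio_cov <- function(bx, sx, by, sy, R) {
  b <- by / bx
  outer_b <- b %o% b
  cov_y <- R * (sy %o% sy)
  cov_x <- R * (sx %o% sx)
  (cov_y + outer_b * cov_x) / (bx %o% bx)
}

#' HEIDI heterogeneity test
#'
#' Tests whether the SMR ratio estimates at multiple instruments in one
#' region are consistent with a single shared causal variant. For each
#' target SNP i, `d_i = b_smr_i - b_smr_top` and `z_d(i) = d_i / SE(d_i)`;
#' the statistic is `T_HEIDI = sum_i z_d(i)^2` over the non-top target
#' SNPs. SE(d_i) and the correlation among the z_d come from the delta
#' method with LD-driven covariance between per-SNP effect estimates; the
#' null distribution (a weighted sum of correlated 1-df chi-squares) is
#' approximated by a moment-matched scaled chi-square (Satterthwaite).
#' A small p-value indicates heterogeneity, i.e. linkage of distinct causal
#' variants rather than one shared variant.
#'
#' @param sumstats_x,sumstats_y exposure/outcome `summary_stats`.
#' @param target character vector of target SNPs (first or `top` is the
#'   top SNP), from [heidi_select()].
#' @param ldref an [ld_reference()].
#' @param top top SNP id (default first element of `target`).
#' @return list `t_heidi`, `p_heidi`, `m` (SNPs used), `dropped` (SNPs
#'   removed for a singular covariance).
#' @export
heidi_test <- function(sumstats_x, sumstats_y, target, ldref,
                       top = target[1]) {
  if (length(target) < 3)
    return(list(t_heidi = NA_real_, p_heidi = NA_real_,
                m = length(target), dropped = character(),
                status = "heidi_skipped_lt3"))
  x <- harmonise_to_ref(sumstats_x, ldref)
  y <- harmonise_to_ref(sumstats_y, ldref)
  ord <- c(top, setdiff(target, top))
  ix <- match(ord, x$SNP); iy <- match(ord, y$SNP)
  bx <- x$BETA[ix]; sx <- x$SE[ix]
  by <- y$BETA[iy]; sy <- y$SE[iy]
  dropped <- character()
  repeat {
    R <- ld_cor(ldref, ord)
    V <- smr_ratio_cov(bx, sx, by, sy, R)
    m <- length(ord)
    # covariance of d_i = b_i - b_top for i = 2..m
    Vd <- V[-1, -1, drop = FALSE] - outer(V[-1, 1], rep(1, m - 1)) -
      outer(rep(1, m - 1), V[1, -1]) + V[1, 1]
    sd_d <- sqrt(diag(Vd))
    if (all(sd_d > 0)) {
      Rd <- Vd / (sd_d %o% sd_d)
      ev <- eigen(Rd, symmetric = TRUE, only.values = TRUE)$values
      if (all(ev > 1e-10)) break
    }
    # singular: drop the non-top SNP most collinear with the rest
    worst <- which.max(vapply(2:m, function(i)
      max(R[i, -i]^2), 0)) + 1L
    dropped <- c(dropped, ord[worst])
    ord <- ord[-worst]; bx <- bx[-worst]; sx <- sx[-worst]
    by <- by[-worst]; sy <- sy[-worst]
    if (length(ord) < 3)
      return(list(t_heidi = NA_real_, p_heidi = NA_real_, m = length(ord),
                  dropped = dropped, status = "heidi_skipped_lt3"))
  }
  b <- by / bx
  d <- b[-1] - b[1]
  zd <- d / sd_d
  t_heidi <- sum(zd^2)
  ev <- pmax(eigen(Rd, symmetric = TRUE, only.values = TRUE)$values, 0)
  mu <- sum(ev)              # = m - 1
  v2 <- 2 * sum(ev^2)
  a <- v2 / (2 * mu)
  g <- 2 * mu^2 / v2
  p <- stats::pchisq(t_heidi / a, g, lower.tail = FALSE)
  list(t_heidi = t_heidi, p_heidi = p, m = length(ord),
       dropped = dropped, status = "ok")
}

#' SMR + HEIDI analysis at a sentinel
#'
#' Runs instrument selection, the SMR test at the top SNP and, when three
#' or more target SNPs are available, the HEIDI heterogeneity test.
#'
#' @inheritParams heidi_select
#' @param p_smr_threshold significance threshold for the SMR test (a
#'   study-specific Bonferroni level; default 0.05).
#' @param p_heidi_threshold below this, sharing of a single variant is
#'   deemed unlikely (default 0.001).
#' @param ... passed to [heidi_select()].
#' @return object of class `smr_result`.
#' @export
smr <- function(sumstats_x, sumstats_y, sentinel, ldref,
                p_smr_threshold = 0.05, p_heidi_threshold = 0.001, ...) {
  selection <- heidi_select(sumstats_x, sumstats_y, sentinel, ldref, ...)
  x <- harmonise_to_ref(sumstats_x, ldref)
  y <- harmonise_to_ref(sumstats_y, ldref)
  it <- match(selection$top_snp, x$SNP)
  io <- match(selection$top_snp, y$SNP)
  st <- smr_test(x$BETA[it], x$SE[it], y$BETA[io], y$SE[io])
  ht <- heidi_test(sumstats_x, sumstats_y, selection$target, ldref,
                   top = selection$top_snp)
  structure(list(
    sentinel = sentinel, top_snp = selection$top_snp,
    b_smr = st$b_smr, t_smr = st$t_smr, p_smr = st$p_smr,
    smr_significant = st$p_smr < p_smr_threshold,
    t_heidi = ht$t_heidi, p_heidi = ht$p_heidi, m = ht$m,
    heidi_call = if (is.na(ht$p_heidi)) NA_character_
    else if (ht$p_heidi >= p_heidi_threshold) "possibly_shared"
    else "sharing_unlikely",
    status = ht$status, target = selection$target,
    rejected = selection$rejected,
    thresholds = c(p_smr = p_smr_threshold, p_heidi = p_heidi_threshold)),
    class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR at sentinel %s (top SNP %s)\n", x$sentinel, x$top_snp))
  cat(sprintf("  b_SMR = %.4f, T_SMR = %.2f, p_SMR = %.3g%s\n",
              x$b_smr, x$t_smr, x$p_smr,
              if (x$smr_significant) " *" else ""))
  if (x$status == "ok")
    cat(sprintf("  HEIDI: T = %.2f over m = %d SNPs, p = %.3g (%s)\n",
                x$t_heidi, x$m, x$p_heidi, x$heidi_call))
  else cat(sprintf("  HEIDI skipped: fewer than 3 target SNPs (m = %d)\n",
                   x$m))
  invisible(x)
}

#' Greedy LD clumping of significant SNPs
#'
#' Keeps the most significant SNP, removes all SNPs with r-squared above
#' `clump_r2` to it, and repeats on the remainder — yielding mutually
#' near-independent index SNPs.
#'
#' @param stats `summary_stats` already filtered to candidate SNPs.
#' @param ldref an [ld_reference()].
#' @param clump_r2 independence threshold (default 0.001).
#' @return character vector of retained SNP ids.
#' @export
clump <- function(stats, ldref, clump_r2 = 0.001) {
  s <- stats[order(stats$P, stats$SNP), , drop = FALSE]
  kept <- character()
  pool <- s$SNP
  while (length(pool)) {
    lead <- pool[1]
    kept <- c(kept, lead)
    if (length(pool) == 1) break
    r2 <- as.numeric(ld_cor(ldref, pool[-1], lead)^2)
    pool <- pool[-1][r2 <= clump_r2]
  }
  kept
}

#' Inverse-variance-weighted Mendelian randomisation
#'
#' Instruments are exposure SNPs at `p_instr` significance, greedily clumped
#' to mutual r-squared at or below `clump_r2`. Each instrument contributes
#' a Wald ratio `beta_out/beta_exp` with SE `se_out/|beta_exp|`; the IVW
#' estimate combines them with inverse-squared-SE weights (a single
#' instrument degenerates to its Wald ratio).
#'
#' @param exposure,outcome `summary_stats` (harmonised internally via the
#'   reference panel's alleles).
#' @param ldref an [ld_reference()].
#' @param p_instr instrument significance threshold (default 5e-8).
#' @param clump_r2 clumping threshold (default 0.001).
#' @param label direction label stored in the result.
#' @return object of class `mr_result`; `status` is "ok" or
#'   "no_instruments".
#' @export
mr_ivw <- function(exposure, outcome, ldref, p_instr = 5e-8,
                   clump_r2 = 0.001, label = "exposure->outcome") {
  x <- harmonise_to_ref(exposure, ldref)
  y <- harmonise_to_ref(outcome, ldref)
  common <- intersect(x$SNP, y$SNP)
  x <- x[match(common, x$SNP), , drop = FALSE]
  y <- y[match(common, y$SNP), , drop = FALSE]
  cand <- x[!is.na(x$P) & x$P < p_instr, , drop = FALSE]
  if (!nrow(cand))
    return(structure(list(direction = label, n_instruments = 0L,
                          status = "no_instruments"), class = "mr_result"))
  instr <- clump(cand, ldref, clump_r2)
  ix <- match(instr, x$SNP); iy <- match(instr, y$SNP)
  wald <- y$BETA[iy] / x$BETA[ix]
  wse <- y$SE[iy] / abs(x$BETA[ix])
  w <- 1 / wse^2
  b <- sum(w * wald) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(
    direction = label, n_instruments = length(instr),
    instruments = data.frame(SNP = instr, wald = wald, se = wse,
                             stringsAsFactors = FALSE),
    ivw_beta = b, ivw_se = se, ivw_p = wald_p(b / se),
    status = "ok"), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("IVW Mendelian randomisation (%s)\n", x$direction))
  if (x$status != "ok") { cat("  no instruments\n"); return(invisible(x)) }
  cat(sprintf("  %d instrument(s); beta = %.4f (SE %.4f), p = %.3g\n",
              x$n_instruments, x$ivw_beta, x$ivw_se, x$ivw_p))
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  if (object$status != "ok") return(NA_real_)
  c(ivw_beta = object$ivw_beta)
}

#' Bidirectional IVW Mendelian randomisation
#'
#' @param stats_a,stats_b `summary_stats` of the two traits.
#' @inheritParams mr_ivw
#' @param labels direction labels.
#' @return list of two `mr_result`s (a->b, b->a).
#' @export
mr_bidirectional <- function(stats_a, stats_b, ldref, p_instr = 5e-8,
                             clump_r2 = 0.001,
                             labels = c("A->B", "B->A")) {
  list(forward = mr_ivw(stats_a, stats_b, ldref, p_instr, clump_r2,
                        label = labels[1]),
       reverse = mr_ivw(stats_b, stats_a, ldref, p_instr, clump_r2,
                        label = labels[2]))
}
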