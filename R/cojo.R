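#' LD reference panel from genotype dosages
#'
#' Wraps a dosage matrix from an external panel of unrelated individuals,
#' giving the SNP-SNP correlations needed for approximate conditional
#' analysis, clumping and HEIDI. Alleles are carried so that summary
#' statistics can be harmonised to the panel before any correlation is used.
#'
#' @param dosages n_ref x m dosage matrix (columns named by SNP id, or
#'   `snp_meta$SNP` used).
#' @param snp_meta data.frame with SNP, CHR, POS, EA, OA.
#' @return object of class `ld_ref` with per-SNP EAF and dosage variance.
#' @export
ld_reference <- function(dosages, snp_meta) {
  dosages <- as.matrix(dosages)
  if (nrow(snp_meta) != ncol(dosages))
    stop_arg("snp_meta rows must match dosage columns")
  colnames(dosages) <- snp_meta$SNP
  structure(list(
    dosages = dosages, snp = snp_meta,
    eaf = colMeans(dosages) / 2,
    var = apply(dosages, 2, stats::var),
    n_ref = nrow(dosages)), class = "ld_ref")
}

#' @export
print.ld_ref <- function(x, ...) {
  cat(sprintf("LD reference: %d individuals x %d SNPs (%s:%s-%s)\n",
              x$n_ref, nrow(x$snp), x$snp$CHR[1],
              min(x$snp$POS), max(x$snp$POS)))
  invisible(x)
}

#' SNP-SNP correlation from an LD reference
#'
#' @param ldref an [ld_reference()].
#' @param ids,ids2 SNP ids; with one set, the square correlation matrix of
#'   that set, with two, the cross-correlation matrix.
#' @return correlation matrix (allele-aligned to the reference panel).
#' @export
ld_cor <- function(ldref, ids, ids2 = NULL) {
  X <- ldref$dosages[, ids, drop = FALSE]
  if (is.null(ids2)) stats::cor(X)
  else stats::cor(X, ldref$dosages[, ids2, drop = FALSE])
}

# Harmonise summary stats to the reference panel's effect alleles.
# Returns the stats subset present in the panel, with BETA/EAF flipped where
# (EA, OA) are swapped; mismatched allele pairs are dropped with a log.
harmonise_to_ref <- function(stats, ldref) {
  common <- intersect(stats$SNP, ldref$snp$SNP)
  s <- stats[match(common, stats$SNP), , drop = FALSE]
  r <- ldref$snp[match(common, ldref$snp$SNP), , drop = FALSE]
  same <- s$EA == r$EA & s$OA == r$OA
  swap <- s$EA == r$OA & s$OA == r$EA
  if (any(swap)) {
    s$BETA[swap] <- -s$BETA[swap]
    s$EAF[swap] <- 1 - s$EAF[swap]
    s$EA[swap] <- r$EA[swap]; s$OA[swap] <- r$OA[swap]
  }
  keep <- same | swap
  attr(s, "dropped_mismatch") <- s$SNP[!keep]
  s[keep, , drop = FALSE]
}

# Reconstructed single-trait normal equations from summary stats + LD ref.
# D_j = (N_j - 1) * Var_ref(g_j)  (equals 2*EAF*(1-EAF)*N under HWE) plays
# the role of the centred X'X diagonal; X'y_j = D_j * beta_j; the phenotypic
# sum of squares y'y is reconstructed per SNP as D_j*se_j^2*(N_j-1) +
# D_j*beta_j^2 and summarised by the median across SNPs, which is robust to
# the few truly associated SNPs.
cojo_setup <- function(stats, ldref) {
  s <- harmonise_to_ref(stats, ldref)
  ok <- !is.na(s$BETA) & !is.na(s$SE) & s$SE > 0
  s <- s[ok, , drop = FALSE]
  v <- ldref$var[s$SNP]
  if (any(v <= 0)) {
    s <- s[v > 0, , drop = FALSE]
    v <- v[v > 0]
  }
  D <- (s$N - 1) * v
  list(stats = s, D = D, Xty = D * s$BETA,
       yy = stats::median(D * s$SE^2 * (s$N - 1) + D * s$BETA^2),
       ldref = ldref)
}

# Joint fit of the SNP set `sel` (integer indices into setup$stats).
joint_fit <- function(setup, sel, lambda = 1) {
  ids <- setup$stats$SNP[sel]
  k <- length(sel)
  R <- ld_cor(setup$ldref, ids)
  sD <- sqrt(setup$D[sel])
  XtX <- R * (sD %o% sD)
  ridge <- FALSE
  B <- tryCatch(solve(XtX, setup$Xty[sel]), error = function(e) NULL)
  if (is.null(B)) {  # singular normal equations: small ridge, flagged
    ridge <- TRUE
    B <- solve(XtX + diag(1e-6 * diag(XtX), k), setup$Xty[sel])
  }
  n <- min(setup$stats$N[sel])
  df <- max(n - k - 1, 1)
  sigma2 <- max((setup$yy - sum(B * setup$Xty[sel])) / df, 1e-12)
  se <- sqrt(pmax(diag(solve(XtX + if (ridge) diag(1e-6 * diag(XtX), k) else 0)), 0) * sigma2)
  if (lambda > 1) se <- se * sqrt(lambda)
  list(snp = ids, b = as.numeric(B), se = se,
       p = wald_p(as.numeric(B) / se), sigma2 = sigma2, n = n,
       ridge = ridge)
}

# Conditional statistics for every SNP not in `sel`, holding the joint
# effects of `sel` fixed. r2_cap marks SNPs too collinear with the
# conditioning set as missing.
cond_stats <- function(setup, sel, r2_cap = 0.9, lambda = 1) {
  s <- setup$stats
  rest <- setdiff(seq_len(nrow(s)), sel)
  out <- data.frame(SNP = s$SNP[rest], CHR = s$CHR[rest], POS = s$POS[rest],
                    EA = s$EA[rest], OA = s$OA[rest], EAF = s$EAF[rest],
                    BETA = NA_real_, SE = NA_real_, P = NA_real_,
                    N = s$N[rest], reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (!length(rest)) return(out)
  if (!length(sel)) {
    out$BETA <- s$BETA[rest]; out$SE <- s$SE[rest]; out$P <- s$P[rest]
    return(out)
  }
  jf <- joint_fit(setup, sel)
  Rcs <- ld_cor(setup$ldref, s$SNP[rest], s$SNP[sel])
  collinear <- apply(Rcs^2, 1, max) > r2_cap
  sDsel <- sqrt(setup$D[sel])
  n <- jf$n
  for (i in seq_along(rest)) {
    j <- rest[i]
    if (collinear[i]) { out$reason[i] <- "collinear"; next }
    cjs <- Rcs[i, ] * sqrt(setup$D[j]) * sDsel      # X'X between j and sel
    num <- setup$Xty[j] - sum(cjs * jf$b)
    b <- num / setup$D[j]
    df <- max(n - length(sel) - 2, 1)
    sigma2 <- max((setup$yy - sum(jf$b * setup$Xty[sel]) - b * num) / df,
                  1e-12)
    se <- sqrt(sigma2 / setup$D[j])
    if (lambda > 1) se <- se * sqrt(lambda)
    out$BETA[i] <- b; out$SE[i] <- se; out$P[i] <- wald_p(b / se)
  }
  out
}

#' Stepwise approximate joint model selection from summary statistics
#'
#' Greedy forward selection in the spirit of summary-statistic conditional
#' and joint analysis: normal equations are reconstructed from the marginal
#' effects, per-SNP heterozygosity-scaled sample sizes and the LD
#' reference's correlations. Starting from the most significant SNP, the
#' remaining SNP with the smallest conditional p-value is added while its
#' conditional p is at or below `p_threshold` and its squared correlation
#' with every selected SNP is at or below `collinearity`; after every
#' addition the joint model is refitted and any selected SNP whose joint p
#' rises above the threshold is dropped. Iterates to convergence.
#'
#' @param stats `summary_stats`/`meta_result` for the region.
#' @param ldref an [ld_reference()] (alleles are harmonised internally).
#' @param p_threshold selection threshold on conditional/joint p.
#' @param collinearity maximum allowed r-squared among selected SNPs
#'   (default 0.9).
#' @param lambda genomic-control inflation factor applied as a post-hoc
#'   scalar to joint/conditional SEs (default 1 = none).
#' @return object of class `cojo_model`: `selected` data.frame (SNP,
#'   marginal and joint effects, joint p), `conditional` stats for all
#'   remaining SNPs given the selected set, `sigma2`, `n`, `log` of skipped
#'   candidates.
#' @export
cojo_slct <- function(stats, ldref, p_threshold, collinearity = 0.9,
                      lambda = 1) {
  setup <- cojo_setup(stats, ldref)
  s <- setup$stats
  log <- data.frame(SNP = character(), reason = character())
  sel <- integer()
  for (iter in seq_len(10L * nrow(s) + 10L)) {
    if (!length(sel)) {
      o <- order(s$P, s$CHR, s$POS, s$SNP)
      if (!length(o) || is.na(s$P[o[1]]) || s$P[o[1]] > p_threshold) break
      sel <- o[1]
    } else {
      cs <- cond_stats(setup, sel, r2_cap = collinearity, lambda = lambda)
      skipped <- cs$SNP[!is.na(cs$reason) & cs$reason == "collinear"]
      skipped <- setdiff(skipped, log$SNP)
      if (length(skipped))
        log <- rbind(log, data.frame(SNP = skipped, reason = "collinear"))
      cs <- cs[!is.na(cs$P), , drop = FALSE]
      if (!nrow(cs)) break
      cs <- cs[order(cs$P, cs$POS, cs$SNP), , drop = FALSE]
      if (cs$P[1] > p_threshold) break
      cand <- match(cs$SNP[1], s$SNP)
      r2 <- ld_cor(setup$ldref, s$SNP[cand], s$SNP[sel])^2
      if (max(r2) > collinearity) {   # defensive; cond_stats already filters
        log <- rbind(log, data.frame(SNP = s$SNP[cand], reason = "collinear"))
        break
      }
      sel <- c(sel, cand)
    }
    repeat {  # backward pass: drop selected SNPs losing joint significance
      jf <- joint_fit(setup, sel, lambda = lambda)
      worst <- which.max(jf$p)
      if (length(sel) > 1 && jf$p[worst] > p_threshold) {
        log <- rbind(log, data.frame(SNP = s$SNP[sel[worst]],
                                     reason = "joint_p_above_threshold"))
        sel <- sel[-worst]
      } else break
    }
  }
  if (length(sel)) {
    jf <- joint_fit(setup, sel, lambda = lambda)
    selected <- data.frame(
      SNP = s$SNP[sel], CHR = s$CHR[sel], POS = s$POS[sel],
      EA = s$EA[sel], OA = s$OA[sel], EAF = s$EAF[sel],
      beta_marginal = s$BETA[sel], se_marginal = s$SE[sel],
      p_marginal = s$P[sel],
      beta_joint = jf$b, se_joint = jf$se, p_joint = jf$p,
      N = s$N[sel], stringsAsFactors = FALSE)
    sigma2 <- jf$sigma2; n <- jf$n; ridge <- jf$ridge
  } else {
    selected <- NULL; sigma2 <- NA_real_; n <- NA_integer_; ridge <- FALSE
  }
  structure(list(
    selected = selected,
    conditional = cond_stats(setup, sel, r2_cap = collinearity,
                             lambda = lambda),
    sigma2 = sigma2, n = n, p_threshold = p_threshold,
    collinearity = collinearity, ridge = ridge, log = log),
    class = "cojo_model")
}

#' @export
print.cojo_model <- function(x, ...) {
  k <- if (is.null(x$selected)) 0L else nrow(x$selected)
  cat(sprintf("Approximate joint model: %d independent signal(s) at p <= %.3g\n",
              k, x$p_threshold))
  if (k) print(x$selected[, c("SNP", "POS", "EAF", "beta_joint", "se_joint",
                              "p_joint")], row.names = FALSE)
  if (x$ridge) cat("  [note] singular normal equations; ridge fallback used\n")
  invisible(x)
}

#' @export
coef.cojo_model <- function(object, ...) {
  if (is.null(object$selected)) return(numeric())
  stats::setNames(object$selected$beta_joint, object$selected$SNP)
}

#' Association statistics conditional on a fixed SNP set
#'
#' Recomputes every remaining SNP's effect, SE and p-value with the joint
#' effects of `condition_on` held fixed, using the same reconstructed normal
#' equations as [cojo_slct()]. Conditioning on an empty set returns the
#' input statistics unchanged; SNPs with r-squared above 0.9 to the
#' conditioning set are emitted as missing with reason "collinear".
#'
#' @param stats `summary_stats` for the region.
#' @param ldref an [ld_reference()].
#' @param condition_on character vector of SNP ids (subset of the panel).
#' @param lambda optional genomic-control scalar on SEs.
#' @return `summary_stats` data.frame of conditional statistics (columns as
#'   the input plus `reason` for missing entries).
#' @export
cojo_cond <- function(stats, ldref, condition_on, lambda = 1) {
  setup <- cojo_setup(stats, ldref)
  if (!length(condition_on)) {
    out <- setup$stats
    out$reason <- NA_character_
    return(out)
  }
  sel <- match(condition_on, setup$stats$SNP)
  if (anyNA(sel)) stop_arg("conditioning SNP(s) not in the reference panel: %s",
                           paste(condition_on[is.na(sel)], collapse = ", "))
  out <- cond_stats(setup, sel, r2_cap = 0.9, lambda = lambda)
  # conditioning SNPs themselves: their residual association given the set's
  # joint effects is exactly zero (normal equations), reported as such
  jf <- joint_fit(setup, sel, lambda = lambda)
  s <- setup$stats
  R <- ld_cor(setup$ldref, s$SNP[sel])
  sD <- sqrt(setup$D[sel])
  num_self <- setup$Xty[sel] - as.numeric((R * (sD %o% sD)) %*% jf$b)
  b_self <- num_self / setup$D[sel]
  se_self <- sqrt(jf$sigma2 / setup$D[sel]) * if (lambda > 1) sqrt(lambda) else 1
  self <- data.frame(SNP = s$SNP[sel], CHR = s$CHR[sel], POS = s$POS[sel],
                     EA = s$EA[sel], OA = s$OA[sel], EAF = s$EAF[sel],
                     BETA = b_self, SE = se_self,
                     P = wald_p(b_self / se_self), N = s$N[sel],
                     reason = "conditioned", stringsAsFactors = FALSE)
  out <- rbind(out, self)
  out[order(match(out$SNP, s$SNP)), , drop = FALSE]
}

#' Proportion of phenotypic variance explained by one SNP
#'
#' `2 * eaf * (1 - eaf) * beta^2 / var_residual`, the additive variance of
#' the SNP on the scale of the covariate-adjusted phenotype residuals.
#'
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta effect estimate per effect allele.
#' @param var_residual variance of the covariate-adjusted phenotype
#'   residuals.
#' @return proportion (symmetric in `eaf` vs `1 - eaf`).
#' @export
variance_explained <- function(eaf, beta, var_residual) {
  if (any(eaf <= 0 | eaf >= 1)) stop_arg("eaf must lie in (0,1)")
  if (any(var_residual <= 0)) stop_arg("var_residual must be > 0")
  2 * eaf * (1 - eaf) * beta^2 / var_residual
}
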