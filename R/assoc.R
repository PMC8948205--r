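#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles via `qnorm((rank - 0.5) / n)`, the
#' transform routinely applied to right-skewed quantitative traits before
#' GWAS so that test statistics are calibrated. Missing values propagate.
#' Ties are averaged by default; `tie_policy = "random"` splits them
#' reproducibly with `seed`.
#'
#' @param values numeric vector (>= 3 non-missing values).
#' @param tie_policy "average" (default) or "random".
#' @param seed integer seed used only when `tie_policy = "random"`.
#' @return transformed vector, approximately mean 0 / variance 1, invariant
#'   to strictly monotone rescaling of the input.
#' @export
rank_inverse_normal <- function(values, tie_policy = c("average", "random"),
                                seed = 1L) {
  tie_policy <- match.arg(tie_policy)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop_arg("need >= 3 non-missing values")
  v <- values[ok]
  if (length(unique(v)) == 1 && tie_policy == "average")
    stop_arg("all values identical: rank transform undefined under tie_policy='average'")
  if (tie_policy == "random") set.seed(as.integer(seed))
  r <- rank(v, ties.method = if (tie_policy == "average") "average" else "random")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Residualise a trait on fixed-effect covariates
#'
#' Ordinary least-squares adjustment for age and sex (or any full-rank
#' covariate matrix); the returned residuals are orthogonal to the fitted
#' design, including the intercept.
#'
#' @param y numeric trait vector.
#' @param covariates data.frame or matrix of covariates (an intercept is
#'   added internally).
#' @return residual vector.
#' @export
adjust_covariates <- function(y, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop_arg("covariate matrix is rank-deficient")
  fit <- stats::lm.fit(X, y)
  as.numeric(fit$residuals)
}

#' Per-SNP additive association scan
#'
#' Simple linear regression of the (already transformed and
#' covariate-adjusted) residuals on each SNP's allele dosage, with a
#' two-sided one-degree-of-freedom Wald test. Monomorphic SNPs are emitted
#' with missing statistics and a reason rather than dropped, so row order
#' matches the input panel.
#'
#' @param residuals centred trait residuals.
#' @param dosages n x m dosage matrix in [0, 2].
#' @param snp_meta data.frame with columns SNP, CHR, POS, EA, OA (one row
#'   per dosage column).
#' @param trait_id,cohort_id labels stored with the result.
#' @return `summary_stats` data.frame with columns SNP, CHR, POS, EA, OA,
#'   EAF, BETA, SE, P, N (P = 2*pnorm(-|BETA/SE|), underflow-guarded).
#' @export
gwas_additive <- function(residuals, dosages, snp_meta,
                          trait_id = "trait", cohort_id = "cohort") {
  dosages <- as.matrix(dosages)
  n <- length(residuals)
  if (nrow(dosages) != n) stop_arg("residuals and dosages disagree on n")
  if (nrow(snp_meta) != ncol(dosages))
    stop_arg("snp_meta rows must match dosage columns")
  y <- residuals - mean(residuals)
  syy <- sum(y^2)
  gbar <- colMeans(dosages)
  sxx <- colSums(dosages^2) - n * gbar^2
  sxy <- as.numeric(crossprod(dosages, y))  # y centred, so equals S_xy
  mono <- sxx <= 0
  beta <- se <- p <- rep(NA_real_, ncol(dosages))
  ok <- !mono
  beta[ok] <- sxy[ok] / sxx[ok]
  sigma2 <- pmax((syy - beta[ok] * sxy[ok]) / (n - 2), 0)
  se[ok] <- sqrt(sigma2 / sxx[ok])
  # perfect fit: residual variance 0; report smallest positive SE so the
  # Wald z stays finite and p hits the underflow guard
  se[ok][se[ok] == 0] <- .Machine$double.xmin
  p[ok] <- wald_p(beta[ok] / se[ok])
  out <- data.frame(
    SNP = snp_meta$SNP, CHR = snp_meta$CHR, POS = snp_meta$POS,
    EA = snp_meta$EA, OA = snp_meta$OA,
    EAF = gbar / 2, BETA = beta, SE = se, P = p, N = n,
    stringsAsFactors = FALSE)
  if (any(mono)) attr(out, "excluded") <-
    data.frame(SNP = snp_meta$SNP[mono], reason = "monomorphic")
  attr(out, "trait_id") <- trait_id
  attr(out, "cohort_id") <- cohort_id
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Nested likelihood-ratio ladder for pQTL vs glyQTL contributions
#'
#' Fits four nested linear models of a glycan trait —
#' M0: covariates only; M1: + pQTL dosage; M2: + glyQTL dosage;
#' M3: + both — by maximum likelihood and returns the three comparisons that
#' separate a protein-abundance effect from a glycosylation-specific effect:
#' M0 vs M1 (does the pQTL associate at all), M1 vs M3 (does the glyQTL add
#' signal once protein level is modelled), M2 vs M3 (does the pQTL add
#' signal once the glyQTL is modelled). Chi-squared tests with 1 df via
#' \code{lmtest::lrtest}.
#'
#' @param y glycan trait vector.
#' @param covariates age/sex data.frame.
#' @param snp_pqtl dosage of the protein-level QTL.
#' @param snp_glyqtl dosage of the glycan-level QTL.
#' @return object of class `lrt_ladder`: log-likelihoods of M0..M3 and a
#'   comparisons data.frame (nested, full, stat, df, p). A `collinear` flag
#'   is set when |cor(pQTL, glyQTL)| > 0.999, in which case M3 is unstable.
#' @export
nested_lrt <- function(y, covariates, snp_pqtl, snp_glyqtl) {
  if (stats::sd(snp_pqtl) == 0 || stats::sd(snp_glyqtl) == 0)
    stop_arg("SNP dosage vectors must be non-constant")
  collinear <- abs(stats::cor(snp_pqtl, snp_glyqtl)) > 0.999
  if (collinear)
    warning("pQTL and glyQTL dosages are collinear (|r| > 0.999); M3 unstable")
  dat <- data.frame(y = y, covariates, pqtl = snp_pqtl, glyqtl = snp_glyqtl)
  cv <- paste(colnames(covariates), collapse = " + ")
  m0 <- stats::lm(stats::as.formula(paste("y ~", cv)), data = dat)
  m1 <- stats::update(m0, . ~ . + pqtl)
  m2 <- stats::update(m0, . ~ . + glyqtl)
  m3 <- stats::update(m0, . ~ . + pqtl + glyqtl)
  comp1 <- lmtest::lrtest(m0, m1)
  comp2 <- lmtest::lrtest(m1, m3)
  comp3 <- lmtest::lrtest(m2, m3)
  grab <- function(lr, a, b) data.frame(
    nested = a, full = b, stat = lr$Chisq[2], df = lr$Df[2],
    p = lr$`Pr(>Chisq)`[2], stringsAsFactors = FALSE)
  structure(list(
    logLik = c(M0 = as.numeric(stats::logLik(m0)),
               M1 = as.numeric(stats::logLik(m1)),
               M2 = as.numeric(stats::logLik(m2)),
               M3 = as.numeric(stats::logLik(m3))),
    comparisons = rbind(grab(comp1, "M0", "M1"),
                        grab(comp2, "M1", "M3"),
                        grab(comp3, "M2", "M3")),
    collinear = collinear), class = "lrt_ladder")
}

#' @export
print.lrt_ladder <- function(x, ...) {
  cat("Nested pQTL/glyQTL likelihood-ratio ladder\n")
  cat("  logLik:", paste(sprintf("%s=%.2f", names(x$logLik), x$logLik),
                         collapse = "  "), "\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %s vs %s: LRT = %.3f (df %d), p = %.3g\n",
                cmp$nested[i], cmp$full[i], cmp$stat[i], cmp$df[i], cmp$p[i]))
  if (x$collinear) cat("  [warning] pQTL and glyQTL nearly collinear\n")
  invisible(x)
}
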