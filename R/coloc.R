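#' Colocalisation priors
#'
#' Per-SNP prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`) and both traits (`p12`), plus the prior variance `W`
#' of the standardised effect under the alternative used by the approximate
#' Bayes factor. Defaults are the method's standard values for quantitative
#' traits: p1 = p2 = 1e-4, p12 = 1e-5, sqrt(W) = 0.15.
#'
#' @param p1,p2,p12 per-SNP priors; requires `0 < p12 <= min(p1, p2)` and a
#'   total well below 1.
#' @param W prior effect variance (default 0.15^2).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.15^2) {
  if (p12 <= 0 || p12 > min(p1, p2))
    stop_arg("require 0 < p12 <= min(p1, p2)")
  if (p1 + p2 + p12 > 0.1)
    stop_arg("priors too large: p1 + p2 + p12 must be well below 1")
  if (W <= 0) stop_arg("W must be > 0")
  structure(list(p1 = p1, p2 = p2, p12 = p12, W = W),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a Normal(0, W) prior
#' on the true effect: `log ABF = 0.5 * (log(1 - r) + r * z^2)` with
#' `r = W / (W + se^2)` and `z = beta/se`. Vectorised.
#'
#' @param beta,se effect estimate and its standard error (> 0).
#' @param W prior effect variance.
#' @return natural-log Bayes factor(s) for association vs no effect.
#' @export
log_abf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) stop_arg("se must be > 0")
  r <- W / (W + se^2)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

#' Approximate-Bayes-factor colocalisation of two traits in one region
#'
#' Given per-SNP summary statistics of two traits over a shared region,
#' computes posterior probabilities of the five hypotheses: H0 no
#' association; H1/H2 association with one trait only; H3 both traits,
#' distinct causal variants; H4 both traits, one shared causal variant.
#' Each hypothesis aggregates per-SNP approximate Bayes factors under the
#' single-causal-variant-per-trait assumption, weighted by the priors;
#' log-sum-exp stabilisation throughout.
#'
#' @param stats1,stats2 `summary_stats` data.frames (intersected on SNP id
#'   internally; alleles are assumed harmonised, and only z^2 enters).
#' @param priors a [coloc_priors()].
#' @return object of class `coloc_res`: `pp` (named PP.H0..PP.H4 summing to
#'   1), `lnabf` per-SNP data.frame (SNP, lABF1, lABF2), `n_snps`,
#'   `priors`.
#' @export
coloc_abf <- function(stats1, stats2, priors = coloc_priors()) {
  common <- intersect(stats1$SNP, stats2$SNP)
  s1 <- stats1[match(common, stats1$SNP), , drop = FALSE]
  s2 <- stats2[match(common, stats2$SNP), , drop = FALSE]
  ok <- !is.na(s1$BETA) & !is.na(s1$SE) & s1$SE > 0 &
        !is.na(s2$BETA) & !is.na(s2$SE) & s2$SE > 0
  s1 <- s1[ok, , drop = FALSE]; s2 <- s2[ok, , drop = FALSE]
  if (!nrow(s1)) stop_arg("no shared SNPs with usable statistics")
  if (nrow(s1) < 10)
    warning(sprintf("only %d shared SNPs; colocalisation may be unreliable",
                    nrow(s1)))
  l1 <- log_abf(s1$BETA, s1$SE, priors$W)
  l2 <- log_abf(s2$BETA, s2$SE, priors$W)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lw <- c(
    H0 = 0,
    H1 = log(priors$p1) + ls1,
    H2 = log(priors$p2) + ls2,
    H3 = log(priors$p1) + log(priors$p2) + logdiffexp(ls1 + ls2, ls12),
    H4 = log(priors$p12) + ls12)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  structure(list(
    pp = stats::setNames(pp, paste0("PP.", names(lw))),
    lnabf = data.frame(SNP = s1$SNP, lABF1 = l1, lABF2 = l2,
                       stringsAsFactors = FALSE),
    n_snps = nrow(s1), priors = priors,
    traits = c(attr(stats1, "trait_id") %||% "trait1",
               attr(stats2, "trait_id") %||% "trait2")),
    class = "coloc_res")
}

#' @export
print.coloc_res <- function(x, ...) {
  cat(sprintf("ABF colocalisation of '%s' vs '%s' (%d SNPs)\n",
              x$traits[1], x$traits[2], x$n_snps))
  cat(" ", paste(sprintf("%s=%.4f", names(x$pp), x$pp), collapse = "  "),
      "\n")
  best <- names(x$pp)[which.max(x$pp)]
  cat(sprintf("  leading hypothesis: %s (%.1f%%)\n", best,
              100 * max(x$pp)))
  invisible(x)
}

#' @export
summary.coloc_res <- function(object, ...) {
  c(object$pp, nsnps = object$n_snps)
}

#' Transitive grouping of traits by pairwise colocalisation
#'
#' Builds the transitive closure of the relation "PP.H4 above threshold":
#' if trait A colocalises with B and B with C, all three land in one group
#' even when the A-C pair falls short. Each group is represented by its
#' trait with the lowest regional p-value.
#'
#' @param traits character vector of trait ids.
#' @param pairwise data.frame with columns `t1`, `t2`, `pp4` for every
#'   tested pair.
#' @param trait_p named numeric: each trait's lowest regional p-value, used
#'   to pick representatives (ties by trait id).
#' @param pp4_threshold edge threshold (default 0.8).
#' @return object of class `coloc_groups`: list `groups` (character
#'   vectors), `representative` per group, `edges` used.
#' @export
coloc_group <- function(traits, pairwise, trait_p, pp4_threshold = 0.8) {
  idx <- stats::setNames(seq_along(traits), traits)
  parent <- seq_along(traits)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- pairwise[!is.na(pairwise$pp4) & pairwise$pp4 > pp4_threshold, ,
                    drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    ri <- find(idx[[edges$t1[k]]]); rj <- find(idx[[edges$t2[k]]])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_along(traits), find, 0L)
  groups <- split(traits, root)
  names(groups) <- NULL
  reps <- vapply(groups, function(g) {
    p <- trait_p[g]
    g[order(p, g)][1]
  }, "")
  structure(list(groups = groups, representative = reps, edges = edges,
                 pp4_threshold = pp4_threshold), class = "coloc_groups")
}

#' @export
print.coloc_groups <- function(x, ...) {
  cat(sprintf("%d colocalisation group(s) (PP.H4 > %.2f, transitive)\n",
              length(x$groups), x$pp4_threshold))
  for (i in seq_along(x$groups))
    cat(sprintf("  group %d [rep %s]: %s\n", i, x$representative[i],
                paste(x$groups[[i]], collapse = ", ")))
  invisible(x)
}

#' Pairwise conditional colocalisation (PwCoCo) for multi-signal loci
#'
#' When either trait carries several conditionally independent signals, a
#' full-vs-full colocalisation can be inconclusive even though one pair of
#' underlying signals is shared. PwCoCo therefore runs [coloc_abf()] on
#' every combination of each trait's full statistics and its statistics
#' conditioned on all but one of its independent signals: with k1 and k2
#' signals this is (k1+1) x (k2+1) runs (nine when both traits carry two
#' signals). Verdict: "colocalises" when any combination reaches PP.H4
#' above `pp_threshold`; "distinct" when every informative combination
#' reaches PP.H3 above it; otherwise "inconclusive".
#'
#' @param stats1,stats2 full regional `summary_stats` of the two traits.
#' @param ldref an [ld_reference()] for conditioning.
#' @param model1,model2 [cojo_slct()] models of the two traits (selected at
#'   genome-wide threshold 5e-8).
#' @param priors a [coloc_priors()].
#' @param pp_threshold posterior-probability evidence threshold (default
#'   0.8).
#' @return object of class `pwcoco_res`: `runs` data.frame (set1, set2,
#'   PP.H0..PP.H4), `verdict`, `k` signal counts.
#' @export
pwcoco <- function(stats1, stats2, ldref, model1, model2,
                   priors = coloc_priors(), pp_threshold = 0.8) {
  sets_for <- function(stats, model) {
    sel <- if (is.null(model$selected)) character() else model$selected$SNP
    out <- list(full = stats)
    for (s in sel) {
      others <- setdiff(sel, s)
      cs <- tryCatch(cojo_cond(stats, ldref, others),
                     error = function(e) NULL)
      out[[paste0("cond_keep_", s)]] <- cs
    }
    out
  }
  sets1 <- sets_for(stats1, model1)
  sets2 <- sets_for(stats2, model2)
  runs <- NULL
  results <- list()
  for (a in names(sets1)) for (b in names(sets2)) {
    s1 <- sets1[[a]]; s2 <- sets2[[b]]
    if (is.null(s1) || is.null(s2)) {
      runs <- rbind(runs, data.frame(set1 = a, set2 = b, PP.H0 = NA,
                                     PP.H1 = NA, PP.H2 = NA, PP.H3 = NA,
                                     PP.H4 = NA))
      next
    }
    res <- suppressWarnings(coloc_abf(s1, s2, priors))
    results[[paste(a, b, sep = " | ")]] <- res
    runs <- rbind(runs, data.frame(set1 = a, set2 = b,
                                   as.list(res$pp), check.names = FALSE))
  }
  informative <- !is.na(runs$PP.H4)
  verdict <- if (any(runs$PP.H4[informative] > pp_threshold)) "colocalises"
  else if (all(runs$PP.H3[informative] > pp_threshold)) "distinct"
  else "inconclusive"
  structure(list(runs = runs, results = results, verdict = verdict,
                 k = c(k1 = length(sets1) - 1L, k2 = length(sets2) - 1L),
                 pp_threshold = pp_threshold), class = "pwcoco_res")
}

#' @export
print.pwcoco_res <- function(x, ...) {
  cat(sprintf("PwCoCo: %d x %d combinations (k1=%d, k2=%d signals)\n",
              x$k[1] + 1L, x$k[2] + 1L, x$k[1], x$k[2]))
  print(x$runs, row.names = FALSE, digits = 4)
  cat(sprintf("  verdict: %s (threshold %.2f)\n", x$verdict, x$pp_threshold))
  invisible(x)
}
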