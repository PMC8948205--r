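# Shared fixtures, built in code and cached for the session.

# GWAS of an already-centred trait with no covariates
quick_gwas <- function(y, cohort, trait = "t", cohort_id = "c") {
  gwas_additive(y - mean(y), cohort$dosages, cohort$snp,
                trait_id = trait, cohort_id = cohort_id)
}

# keep the allele metadata when subsetting a haplotype panel
panel_subset <- function(panel, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(panel))
  cols <- cols %||% seq_len(ncol(panel))
  out <- panel[rows, cols, drop = FALSE]
  attr(out, "alleles") <- attr(panel, "alleles")[cols, , drop = FALSE]
  attr(out, "maf_target") <- attr(panel, "maf_target")[cols]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one LD-structured panel shared across tests (60 SNPs, decay 10)
ld_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_haplotypes(12000, 60, c(0.1, 0.5), 10, seed = 424)
    cache
  }
})

# near-independent panel (low LD) for clumping / orthogonal tests
indep_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_haplotypes(12000, 40, c(0.2, 0.5), 0.2, seed = 425)
    cache
  }
})

# synthetic summary stats with given z-scores (se = s), for oracle tests
toy_stats <- function(z, se = 0.03, trait = "t", pos = NULL) {
  m <- length(z)
  data.frame(SNP = sprintf("s%03d", seq_len(m)), CHR = "1",
             POS = pos %||% (1e6 + (seq_len(m) - 1) * 1000),
             EA = "A", OA = "G", EAF = 0.3, BETA = z * se, SE = se,
             P = 2 * pnorm(-abs(z)), N = 1000, stringsAsFactors = FALSE)
}

# brute-force enumeration of coloc posteriors over causal configurations
coloc_enumerate <- function(l1, l2, priors) {
  m <- length(l1)
  w <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(m)) {
    w["H1"] <- w["H1"] + priors$p1 * exp(l1[i])
    w["H2"] <- w["H2"] + priors$p2 * exp(l2[i])
    w["H4"] <- w["H4"] + priors$p12 * exp(l1[i] + l2[i])
    for (j in seq_len(m)) if (j != i)
      w["H3"] <- w["H3"] + priors$p1 * priors$p2 * exp(l1[i] + l2[j])
  }
  w / sum(w)
}
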