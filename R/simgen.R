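#' Describe a synthetic two-protein glycan-QTL study
#'
#' A scenario fixes everything needed to generate reproducible synthetic
#' cohorts: the marker panel (size, allele-frequency range, LD decay,
#' positions), the trait panels of the two proteins, the causal architecture
#' (which SNP drives which trait and how strongly, on the standardised latent
#' scale), covariate effects, residual noise and the master seed.
#'
#' The generator emulates a two-cohort glycomics GWAS design: each protein's
#' glycome is measured as a panel of chromatographic peak areas (relative
#' abundances after total-area normalisation), and causal variants act
#' additively on a latent standardised scale that is then exponentiated into
#' strictly positive raw peak areas.
#'
#' @param n_individuals integer vector, one entry per cohort (default two
#'   cohorts of 1000, mirroring two isolate cohorts of ~1000 genotyped
#'   samples each).
#' @param n_snps number of biallelic SNPs in the simulated region.
#' @param maf_range interval in (0, 0.5] from which per-SNP target minor
#'   allele frequencies are drawn uniformly.
#' @param ld_decay correlation half-length in SNP units: latent haplotype
#'   correlation between SNPs i and j is exp(-|i-j|/ld_decay).
#' @param causal_map data.frame with columns `snp_index`, `trait_id`, `beta`
#'   (effect per standardised dosage on the latent trait scale).
#' @param proteins named list; each element a list with `prefix` (trait-name
#'   stem) and `n_traits`. Defaults to 35 transferrin peaks (TfGP1..35) and
#'   24 IgG peaks (GP1..24).
#' @param covariate_effects numeric `c(age = ..., sex = ...)`, the latent
#'   effect per year of age and for sex = 1, applied to every trait.
#' @param noise_sd residual standard deviation of the latent trait.
#' @param latent_scale log10 units of raw peak area per latent unit.
#' @param batch_count number of technical batches; 1 disables batch effects.
#' @param pos_step base-pair spacing between adjacent SNPs.
#' @param chr chromosome label.
#' @param pos_start position of the first SNP (1-based bp).
#' @param seed master integer seed; identical scenarios with identical seeds
#'   reproduce byte-identical cohorts.
#' @return An object of class `sim_scenario`.
#' @seealso [simulate.sim_scenario()], [simulate_haplotypes()],
#'   [simulate_cohort()], [simulate_glycans()]
#' @export
sim_scenario <- function(n_individuals = c(1000L, 1000L),
                         n_snps = 251L,
                         maf_range = c(0.05, 0.5),
                         ld_decay = 15,
                         causal_map = data.frame(snp_index = integer(),
                                                 trait_id = character(),
                                                 beta = numeric()),
                         proteins = list(
                           TF  = list(prefix = "TfGP", n_traits = 35L),
                           IgG = list(prefix = "GP",   n_traits = 24L)),
                         covariate_effects = c(age = 0.005, sex = 0.1),
                         noise_sd = 1,
                         latent_scale = 0.15,
                         batch_count = 1L,
                         pos_step = 2000L,
                         chr = "1",
                         pos_start = 1000000L,
                         seed = 1L) {
  if (any(n_individuals < 1)) stop_arg("n_individuals must be positive")
  if (n_snps < 1) stop_arg("n_snps must be positive")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_arg("maf_range must be an interval within (0, 0.5]")
  if (ld_decay <= 0) stop_arg("ld_decay must be > 0")
  if (noise_sd <= 0) stop_arg("noise_sd must be > 0")
  traits <- do.call(rbind, lapply(names(proteins), function(p) {
    data.frame(trait_id = paste0(proteins[[p]]$prefix,
                                 seq_len(proteins[[p]]$n_traits)),
               protein = p, stringsAsFactors = FALSE)
  }))
  if (nrow(causal_map)) {
    if (any(causal_map$snp_index < 1 | causal_map$snp_index > n_snps))
      stop_arg("causal_map snp_index out of range 1..%d", n_snps)
    if (any(!is.finite(causal_map$beta)))
      stop_arg("causal effect sizes must be finite")
    bad <- setdiff(causal_map$trait_id, traits$trait_id)
    if (length(bad))
      stop_arg("causal_map names unknown trait(s): %s",
               paste(bad, collapse = ", "))
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_decay = ld_decay,
    causal_map = causal_map, proteins = proteins, traits = traits,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd, latent_scale = latent_scale,
    batch_count = as.integer(batch_count),
    pos_step = as.integer(pos_step), chr = as.character(chr),
    pos_start = as.integer(pos_start), seed = as.integer(seed)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Synthetic glycan-QTL scenario\n")
  cat(sprintf("  cohorts: %s individuals; %d SNPs (%s:%d-%d)\n",
              paste(x$n_individuals, collapse = " + "), x$n_snps, x$chr,
              x$pos_start, x$pos_start + (x$n_snps - 1L) * x$pos_step))
  cat(sprintf("  traits: %s\n", paste(
    vapply(names(x$proteins),
           function(p) sprintf("%s=%d", p, x$proteins[[p]]$n_traits), ""),
    collapse = ", ")))
  cat(sprintf("  causal entries: %d; ld_decay=%g SNPs; noise_sd=%g; seed=%d\n",
              nrow(x$causal_map), x$ld_decay, x$noise_sd, x$seed))
  invisible(x)
}

#' Simulate an LD-structured haplotype panel
#'
#' Haplotypes are generated from a latent first-order autoregressive Gaussian
#' process along the SNP index: for haplotype h, z_1 ~ N(0,1) and
#' z_j = rho * z_{j-1} + sqrt(1 - rho^2) * e_j with rho = exp(-1/ld_decay),
#' so that cor(z_i, z_j) = exp(-|i-j|/ld_decay). The allele at SNP j is
#' 1 when z_j exceeds the upper quantile of its target frequency p_j, drawn
#' uniformly from `maf_range`. Allele correlation therefore decays
#' approximately as exp(-distance/ld_decay) (attenuated by dichotomisation).
#'
#' @param n_hap number of haplotypes (rows); at least 4.
#' @param n_snps number of SNPs (columns).
#' @param maf_range interval within (0, 0.5] for target allele-1 frequencies.
#' @param ld_decay correlation half-length in SNP units (> 0).
#' @param seed integer seed.
#' @return 0/1 matrix `n_hap x n_snps` with attributes `maf_target`
#'   (per-SNP target frequency) and `alleles` (per-SNP effect/other allele
#'   labels).
#' @export
simulate_haplotypes <- function(n_hap, n_snps, maf_range = c(0.05, 0.5),
                                ld_decay = 15, seed = 1L) {
  if (n_hap < 4) stop_arg("n_hap must be >= 4")
  if (n_snps < 1) stop_arg("n_snps must be >= 1")
  if (ld_decay <= 0) stop_arg("ld_decay must be > 0")
  set.seed(as.integer(seed))
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  rho <- exp(-1 / ld_decay)
  z <- matrix(0, n_hap, n_snps)
  z[, 1] <- stats::rnorm(n_hap)
  if (n_snps > 1) {
    innov_sd <- sqrt(1 - rho^2)
    for (j in 2:n_snps)
      z[, j] <- rho * z[, j - 1] + innov_sd * stats::rnorm(n_hap)
  }
  thr <- stats::qnorm(1 - p)
  H <- matrix(0L, n_hap, n_snps)
  for (j in seq_len(n_snps)) H[, j] <- as.integer(z[, j] > thr[j])
  base <- c("A", "C", "G", "T")
  ea <- base[1 + (seq_len(n_snps) - 1) %% 4]
  oa <- base[1 + seq_len(n_snps) %% 4]
  attr(H, "maf_target") <- p
  attr(H, "alleles") <- data.frame(EA = ea, OA = oa,
                                   stringsAsFactors = FALSE)
  H
}

#' Draw a diploid cohort from a haplotype panel
#'
#' Each individual receives two haplotypes sampled from the panel (without
#' replacement by default, so a panel used for several cohorts must be large
#' enough); the dosage is their sum. Age (years, uniform 20-80, rounded) and
#' sex (0/1, balanced Bernoulli) covariates are drawn alongside.
#'
#' @param panel haplotype matrix from [simulate_haplotypes()].
#' @param n_individuals cohort size.
#' @param seed integer seed.
#' @param replace sample haplotypes with replacement (must be set explicitly
#'   when the panel holds fewer than `2 * n_individuals` haplotypes).
#' @param snp_ids,chr,pos optional SNP metadata; defaults give ids
#'   `snp00001...`, chromosome "1" and positions `1e6 + (j-1)*2000`.
#' @param cohort_id label stored with the cohort.
#' @return An object of class `cohort`: list with `dosages` (n x m, values
#'   0/1/2), `snp` (id/chr/pos/EA/OA data.frame), `covariates`
#'   (age, sex) and `cohort_id`.
#' @export
simulate_cohort <- function(panel, n_individuals, seed = 1L, replace = FALSE,
                            snp_ids = NULL, chr = "1", pos = NULL,
                            cohort_id = "cohort1") {
  n_hap <- nrow(panel)
  m <- ncol(panel)
  if (!replace && n_hap < 2 * n_individuals)
    stop_arg(paste0("panel has %d haplotypes; %d needed without replacement",
                    " (set replace = TRUE to allow resampling)"),
             n_hap, 2 * n_individuals)
  set.seed(as.integer(seed))
  idx <- sample.int(n_hap, 2 * n_individuals, replace = replace)
  dos <- panel[idx[seq_len(n_individuals)], , drop = FALSE] +
    panel[idx[n_individuals + seq_len(n_individuals)], , drop = FALSE]
  age <- round(stats::runif(n_individuals, 20, 80))
  sex <- stats::rbinom(n_individuals, 1, 0.5)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(m))
  if (is.null(pos)) pos <- 1000000L + (seq_len(m) - 1L) * 2000L
  al <- attr(panel, "alleles")
  if (is.null(al)) al <- data.frame(EA = rep("A", m), OA = rep("G", m))
  colnames(dos) <- snp_ids
  structure(list(
    dosages = dos,
    snp = data.frame(SNP = snp_ids, CHR = as.character(chr), POS = pos,
                     EA = al$EA, OA = al$OA, stringsAsFactors = FALSE),
    covariates = data.frame(age = age, sex = sex),
    cohort_id = cohort_id), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort '%s': %d individuals x %d SNPs\n",
              x$cohort_id, nrow(x$dosages), ncol(x$dosages)))
  if (!is.null(x$phenotypes))
    cat(sprintf("  phenotype panels: %s\n",
                paste(sprintf("%s (%d traits)", names(x$phenotypes),
                              vapply(x$phenotypes, ncol, 0L)),
                      collapse = ", ")))
  invisible(x)
}

#' Generate raw glycan peak areas for one protein panel
#'
#' The latent value of trait t for individual i is
#' `sum_c beta_c * std(dosage_c) + age_beta * age + sex_beta * sex +
#'  N(0, noise_sd)`, where `std()` standardises the dosage to unit variance
#' and the sum runs over the causal SNPs mapped to t. The raw peak area is
#' `10^(mu_t + latent_scale * latent)`, with `mu_t` a fixed per-trait
#' baseline log10 abundance, so areas are strictly positive and the
#' downstream total-area normalisation + log10 recovers the latent signal up
#' to a compositional term. With `batch_count > 1` a per-batch, per-trait
#' offset (sd 0.05 latent units) is added and batch labels are attached; no
#' batch correction is applied downstream.
#'
#' @param cohort a [simulate_cohort()] object.
#' @param scenario a [sim_scenario()].
#' @param protein which protein panel of the scenario to generate.
#' @param seed integer seed for noise (and batch assignment).
#' @return matrix `n_individuals x n_traits` of raw peak areas; traits with
#'   zero total variance are flagged in attribute `degenerate`.
#' @export
simulate_glycans <- function(cohort, scenario, protein = names(scenario$proteins)[1],
                             seed = scenario$seed) {
  tr <- scenario$traits[scenario$traits$protein == protein, , drop = FALSE]
  if (!nrow(tr)) stop_arg("no traits for protein '%s'", protein)
  n <- nrow(cohort$dosages)
  J <- nrow(tr)
  cm <- scenario$causal_map
  if (nrow(cm) && any(cm$snp_index > ncol(cohort$dosages)))
    stop_arg("causal_map inconsistent with cohort dimensions")
  set.seed(as.integer(seed))
  age <- cohort$covariates$age
  sex <- cohort$covariates$sex
  ce <- scenario$covariate_effects
  latent <- matrix(stats::rnorm(n * J, 0, scenario$noise_sd), n, J)
  latent <- latent + outer(age, rep(ce[["age"]], J)) +
    outer(sex, rep(ce[["sex"]], J))
  for (j in seq_len(J)) {
    rows <- cm[cm$trait_id == tr$trait_id[j], , drop = FALSE]
    if (!nrow(rows)) next
    for (k in seq_len(nrow(rows))) {
      g <- cohort$dosages[, rows$snp_index[k]]
      sdg <- stats::sd(g)
      if (sdg == 0) next  # monomorphic in this cohort: no phenotypic effect
      latent[, j] <- latent[, j] + rows$beta[k] * (g - mean(g)) / sdg
    }
  }
  batch <- NULL
  if (scenario$batch_count > 1) {
    batch <- sample(rep_len(seq_len(scenario$batch_count), n))
    off <- matrix(stats::rnorm(scenario$batch_count * J, 0, 0.05),
                  scenario$batch_count, J)
    latent <- latent + off[batch, , drop = FALSE]
  }
  # fixed decreasing baseline abundances, ~ 5% down to ~0.5% shares
  mu <- seq(-1.0, -2.0, length.out = J)
  raw <- 10^(sweep(scenario$latent_scale * latent, 2, mu, "+"))
  colnames(raw) <- tr$trait_id
  degenerate <- tr$trait_id[apply(raw, 2, stats::var) == 0]
  attr(raw, "degenerate") <- degenerate
  if (!is.null(batch)) attr(raw, "batch") <- batch
  raw
}

#' Total-area normalisation and log10 transform of glycan peaks
#'
#' Divides each sample's peak areas by their total (so each row of the
#' normalised matrix sums to 1: relative abundances in the glycosylation
#' profile) and returns the log10 of the normalised values. Right-skew and
#' multiplicative measurement error motivate the log scale. Batch correction
#' is deliberately not applied.
#'
#' @param raw strictly positive matrix, samples x traits.
#' @return matrix of log10 relative abundances, invariant to per-sample
#'   rescaling of the raw areas.
#' @export
preprocess_glycans <- function(raw) {
  raw <- as.matrix(raw)
  bad <- which(raw <= 0 | !is.finite(raw), arr.ind = TRUE)
  if (nrow(bad))
    stop_arg("non-positive peak area at sample %s, trait %s",
             rownames(raw)[bad[1, 1]] %||% bad[1, 1],
             colnames(raw)[bad[1, 2]] %||% bad[1, 2])
  log10(raw / rowSums(raw))
}

#' Simulate the full scenario: panel, cohorts, phenotypes, LD reference
#'
#' Generates one haplotype panel and draws every cohort (plus, optionally, an
#' external LD reference cohort) from it with disjoint haplotypes, mimicking
#' populations that share LD structure. Per cohort, raw and preprocessed
#' phenotype panels are produced for each protein.
#'
#' @param object a [sim_scenario()].
#' @param nsim unused (one realisation per call; vary `seed` to replicate).
#' @param seed overrides the scenario seed.
#' @param n_ref individuals in the external LD reference cohort (0 = none).
#' @param ... unused.
#' @return list with `panel`, `cohorts` (each a `cohort` with `$phenotypes`
#'   = per-protein log10 relative abundances and `$raw`), and `ldref`
#'   (an [ld_reference()] or NULL).
#' @export
simulate.sim_scenario <- function(object, nsim = 1, seed = NULL, ...,
                                  n_ref = 0L) {
  sc <- object
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  n_coh <- length(sc$n_individuals)
  n_hap <- 2L * (sum(sc$n_individuals) + n_ref)
  panel <- simulate_haplotypes(n_hap, sc$n_snps, sc$maf_range, sc$ld_decay,
                               seed = sc$seed)
  pos <- sc$pos_start + (seq_len(sc$n_snps) - 1L) * sc$pos_step
  ids <- sprintf("snp%05d", seq_len(sc$n_snps))
  offset <- 0L
  take <- function(k) {
    rows <- offset + seq_len(2L * k)
    offset <<- offset + 2L * k
    panel[rows, , drop = FALSE]
  }
  cohorts <- vector("list", n_coh)
  for (i in seq_len(n_coh)) {
    sub <- take(sc$n_individuals[i])
    attr(sub, "alleles") <- attr(panel, "alleles")
    ch <- simulate_cohort(sub, sc$n_individuals[i], seed = sc$seed + 101L * i,
                          snp_ids = ids, chr = sc$chr, pos = pos,
                          cohort_id = paste0("cohort", i))
    ch$raw <- list()
    ch$phenotypes <- list()
    for (p in names(sc$proteins)) {
      raw <- simulate_glycans(ch, sc, protein = p,
                              seed = sc$seed + 101L * i + match(p, names(sc$proteins)))
      ch$raw[[p]] <- raw
      ch$phenotypes[[p]] <- preprocess_glycans(raw)
    }
    cohorts[[i]] <- ch
  }
  ldref <- NULL
  if (n_ref > 0) {
    sub <- take(n_ref)
    attr(sub, "alleles") <- attr(panel, "alleles")
    ref <- simulate_cohort(sub, n_ref, seed = sc$seed + 997L,
                           snp_ids = ids, chr = sc$chr, pos = pos,
                           cohort_id = "ldref")
    ldref <- ld_reference(ref$dosages, ref$snp)
  }
  list(panel = panel, cohorts = cohorts, ldref = ldref)
}
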