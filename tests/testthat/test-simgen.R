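test_that("haplotype frequencies hit their targets and LD follows the decay parameter", {
  H <- simulate_haplotypes(20000, 50, c(0.05, 0.5), ld_decay = 10, seed = 1)
  maf <- colMeans(H)
  expect_true(all(maf > 0.03 & maf < 0.52))

  # independence limit: vanishing decay length gives uncorrelated SNPs
  H0 <- simulate_haplotypes(5000, 20, c(0.2, 0.5), ld_decay = 1e-6, seed = 2)
  r2 <- cor(H0)[upper.tri(diag(20))]^2
  expect_lt(mean(r2), 0.005)

  # perfect-LD limit: huge decay length with equal frequencies duplicates
  # adjacent SNPs
  H1 <- simulate_haplotypes(5000, 10, c(0.4, 0.4), ld_decay = 1e6, seed = 3)
  adj <- sapply(1:9, function(j) cor(H1[, j], H1[, j + 1])^2)
  expect_true(all(adj > 0.99))

  expect_error(simulate_haplotypes(2, 10, c(0.1, 0.5), 5), "n_hap")
  expect_error(simulate_haplotypes(10, 10, c(0.1, 0.5), 0), "ld_decay")
})

test_that("cohort sampling is Hardy-Weinberg consistent and respects degenerate panels", {
  zeros <- matrix(0L, 100, 5)
  expect_true(all(simulate_cohort(zeros, 50, seed = 1)$dosages == 0))
  ones <- matrix(1L, 100, 5)
  expect_true(all(simulate_cohort(ones, 50, seed = 1)$dosages == 2))
  expect_error(simulate_cohort(zeros, 60, seed = 1), "replace")

  ch <- simulate_cohort(ld_panel(), 5000, seed = 7, replace = TRUE)
  for (j in c(5, 25, 50)) {
    p <- mean(ld_panel()[, j])
    obs <- tabulate(ch$dosages[, j] + 1, nbins = 3)
    expc <- 5000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    gof <- sum((obs - expc)^2 / expc)
    expect_lt(gof, qchisq(0.999, df = 2))
  }
})

test_that("glycan generator is null-calibrated and recovers planted effects", {
  sc_null <- sim_scenario(n_individuals = 800, n_snps = 40,
                          proteins = list(TF = list(prefix = "TfGP",
                                                    n_traits = 5)),
                          ld_decay = 5, seed = 31)
  ch <- simulate_cohort(panel_subset(ld_panel(), 1:1600, 1:40), 800,
                        seed = 32)
  raw <- simulate_glycans(ch, sc_null, "TF", seed = 33)
  y <- rank_inverse_normal(preprocess_glycans(raw)[, 1])
  r <- adjust_covariates(y, ch$covariates)
  ss <- gwas_additive(r, ch$dosages, ch$snp)
  expect_gte(mean(abs(ss$BETA / ss$SE) < 4), 0.99)

  # planted effect on a low-abundance trait: slope of log10 relative
  # abundance per standardised dosage is latent_scale * beta, up to the
  # trait's small compositional share
  cm <- data.frame(snp_index = 20L, trait_id = "TfGP5", beta = 0.5)
  sc <- sim_scenario(n_individuals = 1000, n_snps = 40, causal_map = cm,
                     proteins = list(TF = list(prefix = "TfGP",
                                               n_traits = 5)),
                     ld_decay = 5, seed = 41)
  ch <- simulate_cohort(panel_subset(ld_panel(), 1601:3601, 1:40), 1000,
                        seed = 42)
  raw <- simulate_glycans(ch, sc, "TF", seed = 43)
  lp <- preprocess_glycans(raw)[, "TfGP5"] / sc$latent_scale
  g <- as.numeric(scale(ch$dosages[, 20]))
  fit <- summary(lm(lp ~ g + ch$covariates$age + ch$covariates$sex))
  expect_lt(abs(fit$coefficients["g", 1] - 0.5),
            3 * fit$coefficients["g", 2] + 0.5 * 0.05)

  # two traits sharing one causal SNP: residual correlation after removing
  # the SNP is near zero when their noise is independent
  cm2 <- rbind(cm, data.frame(snp_index = 20L, trait_id = "TfGP4",
                              beta = 0.4))
  sc2 <- sim_scenario(n_individuals = 1000, n_snps = 40, causal_map = cm2,
                      proteins = list(TF = list(prefix = "TfGP",
                                                n_traits = 5)),
                      covariate_effects = c(age = 0, sex = 0),
                      ld_decay = 5, seed = 51)
  raw2 <- simulate_glycans(ch, sc2, "TF", seed = 52)
  g <- ch$dosages[, 20]
  r4 <- resid(lm(log10(raw2[, "TfGP4"]) ~ g))
  r5 <- resid(lm(log10(raw2[, "TfGP5"]) ~ g))
  expect_lt(abs(cor(r4, r5)), 3 / sqrt(1000))
})

test_that("total-area normalisation does hand arithmetic and is scale invariant", {
  m <- matrix(c(2, 2, 4), 1, 3, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(as.numeric(preprocess_glycans(m)),
               log10(c(0.25, 0.25, 0.5)), tolerance = 1e-12)
  single <- matrix(c(3, 7, 0.4), 3, 1)
  expect_equal(as.numeric(preprocess_glycans(single)), c(0, 0, 0))
  m2 <- matrix(runif(30, 1, 5), 10, 3)
  scaled <- m2 * runif(10, 0.1, 10)   # per-sample multiplicative scaling
  expect_equal(preprocess_glycans(m2), preprocess_glycans(scaled),
               tolerance = 1e-12)
  m2[3, 2] <- 0
  colnames(m2) <- c("t1", "t2", "t3")
  expect_error(preprocess_glycans(m2), "t2")
})

test_that("identical scenario and seed reproduce bit-identical cohorts", {
  sc <- scenario_shared(seed = 9)
  a <- simulate(sc, n_ref = 100)
  b <- simulate(sc, n_ref = 100)
  expect_identical(a$cohorts[[1]]$dosages, b$cohorts[[1]]$dosages)
  expect_identical(a$cohorts[[2]]$raw, b$cohorts[[2]]$raw)
  expect_identical(a$ldref$dosages, b$ldref$dosages)
  c2 <- simulate(sc, seed = 10, n_ref = 100)
  expect_false(identical(a$cohorts[[1]]$dosages, c2$cohorts[[1]]$dosages))
})
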