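test_that("SMR statistic follows its algebraic identities and chi-square tail", {
  # z_y = 0: no outcome association, T = 0, p = 1
  r0 <- smr_test(0.5, 0.05, 0, 0.05)
  expect_equal(r0$t_smr, 0)
  expect_equal(r0$p_smr, 1)

  # z_x = z_y = z: T = z^2 / 2
  r1 <- smr_test(0.4, 0.1, 0.4, 0.1)
  expect_equal(r1$t_smr, (0.4 / 0.1)^2 / 2, tolerance = 1e-12)

  # exposure measured without error: T tends to z_y^2
  r2 <- smr_test(1, 1e-9, 0.3, 0.1)
  expect_equal(r2$t_smr, 9, tolerance = 1e-6)

  # p equals the chi-square(1) upper tail to 1e-12 relative
  r3 <- smr_test(0.3, 0.05, 0.12, 0.04)
  expect_equal(r3$p_smr, pchisq(r3$t_smr, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r3$b_smr, 0.12 / 0.3)
  expect_error(smr_test(0, 0.05, 0.1, 0.05), "undefined")
})

test_that("instrument selection caps, rejects by LD, and follows the manual trace", {
  # 30 mutually independent eligible SNPs: target capped at exactly 20
  ch <- simulate_cohort(panel_subset(indep_panel(), NULL, 1:30), 3000,
                        seed = 151)
  ldref <- ld_reference(ch$dosages, ch$snp)
  set.seed(152)
  zx <- runif(30, 6, 12) * sign(rnorm(30))
  sx <- quick_gwas(rnorm(3000), ch); sy <- quick_gwas(rnorm(3000), ch)
  sx$BETA <- zx * sx$SE
  sx$P <- 2 * pnorm(-abs(zx))
  sel <- heidi_select(sx, sy, sx$SNP[which.min(sx$P)], ldref)
  expect_equal(length(sel$target), 20)
  expect_equal(sel$status, "ok")

  # all eligible SNPs in perfect LD: target reduces to the top SNP
  dup <- ch$dosages[, rep(1, 6)]
  snp6 <- ch$snp[rep(1, 6), ]; snp6$SNP <- paste0("d", 1:6)
  colnames(dup) <- snp6$SNP
  ldref2 <- ld_reference(dup, snp6)
  y2 <- as.numeric(0.3 * scale(dup[, 1])) + rnorm(3000)
  sx2 <- gwas_additive(y2 - mean(y2), dup, snp6)
  sy2 <- sx2
  sel2 <- heidi_select(sx2, sy2, "d1", ldref2)
  expect_equal(sel2$target, sel2$top_snp)
  expect_equal(sel2$status, "heidi_skipped_lt3")

  # hand-built 6-SNP set: duplicates of each accepted SNP must be rejected
  base <- ch$dosages[, c(1, 1, 2, 2, 3, 3)]
  snps <- ch$snp[c(1, 1, 2, 2, 3, 3), ]
  snps$SNP <- c("T1", "S2", "S3", "S4", "S5", "S6")
  colnames(base) <- snps$SNP
  ldref3 <- ld_reference(base, snps)
  mk <- function(z) {
    s <- data.frame(SNP = snps$SNP, CHR = snps$CHR, POS = snps$POS,
                    EA = snps$EA, OA = snps$OA,
                    EAF = colMeans(base) / 2, BETA = z * 0.03, SE = 0.03,
                    P = 2 * pnorm(-abs(z)), N = 3000)
    s
  }
  # primary z decreasing T1 > S2 > ...; outcome z chosen so P_SMR orders
  # S2 < S3 < S4 < S5 < S6 (T_SMR dominated by the smaller |z|)
  sx3 <- mk(c(12, 11, 10, 9, 8, 7))
  sy3 <- mk(c(12, 10, 9, 8, 7, 6))
  sel3 <- heidi_select(sx3, sy3, "T1", ldref3)
  # trace: top = T1 (lowest primary p); S2 duplicates T1 -> rejected;
  # S3 independent -> target; S4 duplicates S3 -> rejected;
  # S5 independent -> target; S6 duplicates S5 -> rejected
  expect_equal(sel3$top_snp, "T1")
  expect_equal(sel3$target, c("T1", "S3", "S5"))
  expect_equal(sel3$rejected, c("S2", "S4", "S6"))

  expect_error(heidi_select(sx3[3:6, ], sy3[3:6, ], "T1", ldref3),
               "no_instrument")
})

test_that("HEIDI is zero for homogeneous ratios and invariant to SNP relabelling", {
  ch <- simulate_cohort(ld_panel(), 3000, seed = 161, replace = TRUE)
  ldref <- ld_reference(ch$dosages, ch$snp)
  set.seed(162)
  g <- as.numeric(scale(ch$dosages[, 30]))
  x <- 0.5 * g + rnorm(3000)
  y <- 0.3 * g + rnorm(3000)
  sx <- quick_gwas(x, ch); sy <- quick_gwas(y, ch)

  # constructed homogeneity: identical ratio at every SNP gives T = 0
  sy_c <- sx
  sy_c$BETA <- 2 * sx$BETA        # b_smr = 2 everywhere
  target <- ch$snp$SNP[c(30, 20, 40, 10)]
  ht <- heidi_test(sx, sy_c, target, ldref)
  expect_equal(ht$t_heidi, 0, tolerance = 1e-9)

  # relabelling the non-top SNPs leaves the statistic unchanged
  h1 <- heidi_test(sx, sy, ch$snp$SNP[c(30, 10, 20, 40, 50)], ldref)
  h2 <- heidi_test(sx, sy, ch$snp$SNP[c(30, 50, 20, 40, 10)], ldref)
  expect_equal(h1$t_heidi, h2$t_heidi, tolerance = 1e-9)
  expect_equal(h1$p_heidi, h2$p_heidi, tolerance = 1e-9)

  # fewer than three SNPs: skipped with status
  h3 <- heidi_test(sx, sy, ch$snp$SNP[c(30, 10)], ldref)
  expect_equal(h3$status, "heidi_skipped_lt3")
  expect_true(is.na(h3$p_heidi))
})

test_that("IVW MR degenerates to the Wald ratio and recovers a causal effect bidirectionally", {
  ch <- simulate_cohort(indep_panel(), 5000, seed = 171, replace = TRUE)
  ldref <- ld_reference(ch$dosages, ch$snp)
  set.seed(172)
  G <- scale(ch$dosages[, 1:20])
  Gy <- scale(ch$dosages[, 21:35])
  x <- as.numeric(G %*% rep(0.15, 20)) + rnorm(5000)
  y <- 0.3 * x + as.numeric(Gy %*% rep(0.2, 15)) + rnorm(5000)
  sx <- quick_gwas(x, ch); sy <- quick_gwas(y, ch)
  mr <- mr_bidirectional(sx, sy, ldref)
  expect_equal(mr$forward$status, "ok")
  expect_gte(mr$forward$n_instruments, 5)
  expect_lt(abs(mr$forward$ivw_beta - 0.3), 3 * mr$forward$ivw_se)
  expect_equal(mr$reverse$status, "ok")
  expect_lt(abs(mr$reverse$ivw_beta), 3 * mr$reverse$ivw_se + 0.02)

  # single instrument: IVW is exactly the Wald ratio
  one <- sx[1, , drop = FALSE]; one$P <- 1e-12; one$BETA <- 0.2; one$SE <- 0.02
  oy <- sy[1, , drop = FALSE]; oy$BETA <- 0.1; oy$SE <- 0.03
  m1 <- mr_ivw(one, oy, ldref)
  expect_equal(m1$ivw_beta, 0.1 / 0.2)
  expect_equal(m1$ivw_se, 0.03 / 0.2)

  # two identical-ratio, equal-se instruments: beta kept, se / sqrt(2)
  two_x <- sx[1:2, ]; two_x$P <- 1e-12; two_x$BETA <- 0.2; two_x$SE <- 0.02
  two_y <- sy[1:2, ]; two_y$BETA <- 0.1; two_y$SE <- 0.03
  m2 <- mr_ivw(two_x, two_y, ldref)
  expect_equal(m2$ivw_beta, 0.5)
  expect_equal(m2$ivw_se, (0.03 / 0.2) / sqrt(2))

  null <- sx; null$P <- 0.5
  expect_equal(mr_ivw(null, sy, ldref)$status, "no_instruments")
})

test_that("greedy clumping keeps the strongest of correlated SNPs", {
  ch <- simulate_cohort(ld_panel(), 3000, seed = 181, replace = TRUE)
  ldref <- ld_reference(ch$dosages, ch$snp)
  set.seed(182)
  g <- as.numeric(scale(ch$dosages[, 30]))
  ss <- quick_gwas(0.5 * g + rnorm(3000), ch)
  sig <- ss[ss$P < 5e-8, ]
  kept <- clump(sig, ldref, clump_r2 = 0.001)
  expect_equal(kept[1], sig$SNP[which.min(sig$P)])
  if (length(kept) > 1) {
    r2 <- ld_cor(ldref, kept)^2
    expect_true(all(r2[upper.tri(r2)] <= 0.001))
  }
})
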