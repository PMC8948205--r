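make_stats <- function(snp, eaf, beta, se, n = 948, ea = "A", oa = "G") {
  data.frame(SNP = snp, CHR = "1", POS = seq_along(snp) * 1000,
             EA = ea, OA = oa, EAF = eaf, BETA = beta, SE = se,
             P = 2 * pnorm(-abs(beta / se)), N = n,
             stringsAsFactors = FALSE)
}

test_that("allele harmonisation recognises swaps and rejects mismatches", {
  a <- make_stats(c("s1", "s2", "s3"), 0.3, 0.1, 0.05)
  b <- make_stats(c("s1", "s2", "s3"), c(0.7, 0.3, 0.3),
                  c(-0.1, 0.1, 0.1), 0.05)
  b$EA[1] <- "G"; b$OA[1] <- "A"         # swapped report
  b$EA[3] <- "C"; b$OA[3] <- "T"         # unresolvable
  h <- harmonise_pair(a, b)
  expect_equal(h$b$BETA[h$b$SNP == "s1"], 0.1)
  expect_equal(h$b$EAF[h$b$SNP == "s1"], 0.3)
  expect_true("s3" %in% h$removed$SNP[h$removed$reason == "allele_mismatch"])
  # after harmonisation, swapped-and-negated cohort is identical to cohort A
  expect_equal(h$a$BETA[1:2], h$b$BETA[1:2])
  expect_equal(h$a$EAF[1:2], h$b$EAF[1:2])
})

test_that("QC removes frequency outliers and low minor allele counts, symmetrically", {
  a <- make_stats(c("s1", "s2", "s3", "s4"), c(0.10, 0.004, 0.003, 0.25),
                  0.1, 0.05)
  b <- make_stats(c("s1", "s2", "s3", "s4"), c(0.45, 0.004, 0.003, 0.25),
                  0.1, 0.05)
  qc <- qc_filter(a, b)
  # |0.10 - 0.45| = 0.35 > 0.3: removed
  expect_true("s1" %in% qc$removed$SNP[qc$removed$reason == "eaf_diff"])
  # MAC arithmetic at N = 948: EAF 0.004 -> 7.584 > 6 retained;
  # 0.003 -> 5.688 <= 6 removed
  expect_equal(2 * 948 * 0.004, 7.584)
  expect_equal(2 * 948 * 0.003, 5.688)
  expect_true("s2" %in% qc$a$SNP)
  expect_true("s3" %in% qc$removed$SNP[grepl("low_mac", qc$removed$reason)])
  expect_equal(sort(qc$a$SNP), c("s2", "s4"))

  # symmetry: swapping cohort order changes no retention decision
  qc2 <- qc_filter(b, a)
  expect_equal(sort(qc2$a$SNP), sort(qc$a$SNP))
})

test_that("IVW meta-analysis matches hand arithmetic and the WLS oracle", {
  a <- make_stats("s1", 0.3, 1, 1, n = 1000)
  b <- make_stats("s1", 0.3, 0, 1, n = 1000)
  m <- ivw_meta(list(a, b))
  expect_equal(m$BETA, 0.5)
  expect_equal(m$SE, 1 / sqrt(2))
  expect_equal(m$N, 2000)

  # identical inputs: same beta, se shrinks by sqrt(2)
  m2 <- ivw_meta(list(a, a))
  expect_equal(m2$BETA, a$BETA)
  expect_equal(m2$SE, a$SE / sqrt(2))

  # GLS oracle on many SNPs and unequal variances
  set.seed(5)
  sa <- make_stats(sprintf("s%02d", 1:20), 0.3, rnorm(20), runif(20, .02, .2))
  sb <- make_stats(sprintf("s%02d", 1:20), 0.3, rnorm(20), runif(20, .02, .2))
  m3 <- ivw_meta(list(sa, sb))
  for (i in c(1, 7, 20)) {
    o <- lm(c(sa$BETA[i], sb$BETA[i]) ~ 1,
            weights = 1 / c(sa$SE[i], sb$SE[i])^2)
    expect_equal(m3$BETA[i], unname(coef(o)), tolerance = 1e-10)
  }
  sa$SE[1] <- 0
  expect_error(ivw_meta(list(sa, sb)), "non-positive")
  # SNPs present in a single cohort are dropped and logged
  sa2 <- make_stats(c("s1", "only"), 0.3, 0.1, 0.05)
  m4 <- ivw_meta(list(sa2, make_stats("s1", 0.3, 0.1, 0.05)))
  expect_equal(attr(m4, "dropped"), "only")
})

test_that("genomic control estimates lambda correctly and never deflates", {
  set.seed(6)
  z <- rnorm(10000)
  m <- make_stats(sprintf("s%05d", 1:10000), 0.3, z, 1)
  class(m) <- c("meta_result", "summary_stats", "data.frame")
  g <- genomic_control(m)
  lam <- attr(g, "lambda_gc")
  expect_gt(lam, 0.95); expect_lt(lam, 1.05)

  # doubling z quadruples lambda; corrected z^2 median returns to 0.4549
  m2 <- m; m2$BETA <- 2 * z
  g2 <- genomic_control(m2)
  expect_equal(attr(g2, "lambda_gc"), 4 * lam, tolerance = 1e-9)
  expect_equal(median((g2$BETA / g2$SE)^2), qchisq(0.5, 1),
               tolerance = 1e-9)

  # lambda <= 1: statistics unchanged, lambda still reported
  m3 <- m; m3$BETA <- 0.5 * z
  g3 <- genomic_control(m3)
  expect_lt(attr(g3, "lambda_gc"), 1)
  expect_identical(g3$SE, m3$SE)
  expect_error(genomic_control(m[1:50, ]), "100")
})

test_that("Bonferroni thresholds reproduce the trait-panel arithmetic", {
  expect_equal(significance_threshold(5e-8, 35)$threshold_3sf, 1.43e-9)
  expect_equal(significance_threshold(5e-8, 24)$threshold_3sf, 2.08e-9)
  expect_equal(significance_threshold(0.037, 1)$threshold, 0.037)
  expect_error(significance_threshold(1.2, 10), "alpha")
})
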