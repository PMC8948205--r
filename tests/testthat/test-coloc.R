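test_that("log ABF matches a numerically integrated Bayes factor", {
  # quadrature oracle: BF = int N(b_hat; b, se^2) N(b; 0, W) db / N(b_hat; 0, se^2)
  quad_labf <- function(beta, se, W) {
    num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, sqrt(W)),
                     -2, 2, rel.tol = 1e-12)$value
    log(num) - dnorm(beta, 0, se, log = TRUE)
  }
  for (case in list(c(0.5, 0.05, 0.0225), c(-0.2, 0.1, 0.04),
                    c(0.02, 0.2, 0.0225)))
    expect_equal(log_abf(case[1], case[2], case[3]),
                 quad_labf(case[1], case[2], case[3]), tolerance = 1e-6)

  # null shrinkage and point-null prior limit
  expect_lt(log_abf(0, 0.1, 0.0225), 0)
  expect_equal(log_abf(3, 0.5, 1e-12), 0, tolerance = 1e-6)
  expect_error(log_abf(1, 0), "se")
})

test_that("posterior weights equal brute-force enumeration over causal configurations", {
  set.seed(131)
  pr <- coloc_priors()
  z1 <- c(rnorm(47), 8, 5, 1)
  z2 <- c(rnorm(47), 7.5, 1, 4)
  s1 <- toy_stats(z1); s2 <- toy_stats(z2)
  res <- coloc_abf(s1, s2, pr)
  enum <- coloc_enumerate(log_abf(s1$BETA, s1$SE, pr$W),
                          log_abf(s2$BETA, s2$SE, pr$W), pr)
  expect_equal(unname(res$pp), unname(enum), tolerance = 1e-10)
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
})

test_that("coloc separates shared from distinct causal signals", {
  set.seed(132)
  z <- c(rnorm(30), 8, rnorm(9))
  s1 <- toy_stats(z)
  res_same <- coloc_abf(s1, s1)
  expect_gt(res_same$pp[["PP.H4"]], 0.99)

  zb <- c(8, rnorm(39))                 # distinct causal position, r = 0
  res_diff <- coloc_abf(s1, toy_stats(zb))
  expect_gt(res_diff$pp[["PP.H3"]], 0.95)

  # trait swap with p1 = p2 permutes H1/H2 and fixes H3/H4
  sw <- coloc_abf(toy_stats(zb), s1)
  expect_equal(sw$pp[["PP.H1"]], res_diff$pp[["PP.H2"]], tolerance = 1e-12)
  expect_equal(sw$pp[["PP.H4"]], res_diff$pp[["PP.H4"]], tolerance = 1e-12)

  # adding a z = 0 SNP to both traits barely moves the posteriors
  s1b <- rbind(s1, toy_stats(0)[1, ])
  s1b$SNP[41] <- "extra"
  s2b <- rbind(toy_stats(zb), toy_stats(0)[1, ])
  s2b$SNP[41] <- "extra"
  res_aug <- coloc_abf(s1b, s2b)
  expect_lt(max(abs(res_aug$pp - res_diff$pp)), 1e-3)

  expect_warning(coloc_abf(s1[1:5, ], s1[1:5, ]), "unreliable")
  expect_error(coloc_abf(s1, toy_stats(1, pos = 1)[0, ]), "no shared")
})

test_that("trait grouping is the transitive closure with lowest-p representatives", {
  tp <- c(A = 1e-20, B = 1e-15, C = 1e-10)
  pw <- data.frame(t1 = c("A", "B", "A"), t2 = c("B", "C", "C"),
                   pp4 = c(0.95, 0.9, 0.2))
  g <- coloc_group(names(tp), pw, tp)
  expect_equal(length(g$groups), 1)
  expect_equal(sort(g$groups[[1]]), c("A", "B", "C"))
  expect_equal(unname(g$representative), "A")

  g2 <- coloc_group(names(tp), transform(pw, pp4 = 0.1), tp)
  expect_equal(length(g2$groups), 3)
  expect_setequal(unname(g2$representative), c("A", "B", "C"))

  g3 <- coloc_group(names(tp), transform(pw, pp4 = 0.99), tp)
  expect_equal(length(g3$groups), 1)
})

test_that("PwCoCo enumerates full and conditioned combinations and finds masked sharing", {
  # identical single-signal traits: (1+1)x(1+1) = 4 runs, all colocalising
  ch <- simulate_cohort(ld_panel(), 2000, seed = 141, replace = TRUE)
  ldref <- ld_reference(ch$dosages, ch$snp)
  set.seed(142)
  g <- as.numeric(scale(ch$dosages[, 30]))
  y <- 0.4 * g + rnorm(2000)
  ss <- quick_gwas(y, ch)
  m1 <- cojo_slct(ss, ldref, 5e-8)
  pw <- pwcoco(ss, ss, ldref, m1, m1)
  expect_equal(nrow(pw$runs), 4)
  expect_equal(pw$verdict, "colocalises")
  expect_true(all(pw$runs$PP.H4 > 0.99))

  # two-signal traits: trait1 causal at (a, b), trait2 at (b, c); the shared
  # signal b is isolated by conditioning, 9 combinations in total
  ch2 <- simulate_cohort(ld_panel(), 5000, seed = 143, replace = TRUE)
  ldref2 <- ld_reference(ch2$dosages, ch2$snp)
  set.seed(144)
  ga <- as.numeric(scale(ch2$dosages[, 10]))
  gb <- as.numeric(scale(ch2$dosages[, 30]))
  gc_ <- as.numeric(scale(ch2$dosages[, 50]))
  y1 <- 0.3 * ga + 0.3 * gb + rnorm(5000)
  y2 <- 0.3 * gb + 0.3 * gc_ + rnorm(5000)
  s1 <- quick_gwas(y1, ch2); s2 <- quick_gwas(y2, ch2)
  mm1 <- cojo_slct(s1, ldref2, 5e-8)
  mm2 <- cojo_slct(s2, ldref2, 5e-8)
  expect_equal(nrow(mm1$selected), 2)
  expect_equal(nrow(mm2$selected), 2)
  pw2 <- pwcoco(s1, s2, ldref2, mm1, mm2)
  expect_equal(nrow(pw2$runs), 9)
  expect_equal(pw2$verdict, "colocalises")
  expect_gt(max(pw2$runs$PP.H4, na.rm = TRUE), 0.8)
})

test_that("prior validation enforces the hierarchy", {
  expect_error(coloc_priors(p12 = 2e-4), "p12")
  expect_error(coloc_priors(p1 = 0.2, p2 = 0.2, p12 = 0.05), "well below")
  expect_error(coloc_priors(W = 0), "W")
})
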