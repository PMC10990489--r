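test_that("beta-prime is the log10 relative-activity ratio", {
  f <- ref_fit("pY653/654", "FGF4")
  expect_equal(beta_prime(f, f)$beta_prime, 0)

  # FGF4: Y653/654 phosphorylation over FRS2 phosphorylation
  bp <- beta_prime(ref_fit("pY653/654", "FGF4"), ref_fit("pFRS2", "FGF4"))
  oracle <- log10((0.95 / 4.77e-10) / (0.94 / 3.42e-10))
  expect_equal(bp$beta_prime, oracle, tolerance = 1e-12)
  expect_equal(round(bp$beta_prime, 3), -0.140)

  # scale invariance: common factor on both Etops cancels
  fn <- ref_fit("pY653/654", "FGF4")
  fd <- ref_fit("pFRS2", "FGF4")
  expect_equal(beta_prime(modifyList(fn, list(etop = fn$etop * 7)),
                          modifyList(fd, list(etop = fd$etop * 7)))$beta_prime,
               bp$beta_prime, tolerance = 1e-12)

  expect_error(beta_prime(modifyList(f, list(etop = -1)), f), "positive")
})

test_that("bias coefficients reproduce known values and identities", {
  b <- bias_coefficient(ref_fit("pFRS2", "FGF4"),
                        ref_fit("pY653/654", "FGF4"),
                        ref_fit("pFRS2", "FGF8"),
                        ref_fit("pY653/654", "FGF8"))
  expect_equal(round(b$beta, 2), -0.61)
  expect_equal(b$beta, b$beta_prime_ligand - b$beta_prime_reference,
               tolerance = 1e-12)

  b2 <- bias_coefficient(ref_fit("collagen2_loss", "FGF4"),
                         ref_fit("growth_arrest", "FGF4"),
                         ref_fit("collagen2_loss", "FGF8"),
                         ref_fit("growth_arrest", "FGF8"))
  expect_equal(round(b2$beta, 2), -1.77)

  # a ligand against itself is unbiased
  self <- bias_coefficient(ref_fit("pFRS2", "FGF4"),
                           ref_fit("pY653/654", "FGF4"),
                           ref_fit("pFRS2", "FGF4"),
                           ref_fit("pY653/654", "FGF4"))
  expect_equal(self$beta, 0)

  # swapping numerator and denominator responses flips the sign
  bswap <- bias_coefficient(ref_fit("pY653/654", "FGF4"),
                            ref_fit("pFRS2", "FGF4"),
                            ref_fit("pY653/654", "FGF8"),
                            ref_fit("pFRS2", "FGF8"))
  expect_equal(bswap$beta, -b$beta, tolerance = 1e-12)
})

test_that("bias is invariant to per-response units and reference-transitive", {
  fits <- fgfr1_fit_parameters()
  map <- data.frame(ligand = "FGF9", reference = "FGF8",
                    response_num = "pFRS2", response_den = "pY653/654")
  b0 <- compute_bias_map(fits, map)$beta

  # multiply one response's Etop by a common constant across all ligands
  fits2 <- fits
  i <- fits2$response == "pFRS2"
  fits2$etop[i] <- fits2$etop[i] * 3.7
  expect_equal(compute_bias_map(fits2, map)$beta, b0, tolerance = 1e-12)

  # transitivity: beta(L1 vs L2) = beta'(L1) - beta'(L2)
  bp4 <- beta_prime(ref_fit("pFRS2", "FGF4"), ref_fit("pY653/654", "FGF4"))
  bp9 <- beta_prime(ref_fit("pFRS2", "FGF9"), ref_fit("pY653/654", "FGF9"))
  b49 <- bias_coefficient(ref_fit("pFRS2", "FGF4"),
                          ref_fit("pY653/654", "FGF4"),
                          ref_fit("pFRS2", "FGF9"),
                          ref_fit("pY653/654", "FGF9"))
  expect_equal(b49$beta, bp4$beta_prime - bp9$beta_prime, tolerance = 1e-12)
})

test_that("error propagation methods agree with direct evaluation", {
  expect_equal(propagate_error(function(x) log10(x), 10, 0), 0)
  expect_equal(propagate_error(function(x) log10(x), 10, 1),
               log10(1.1), tolerance = 1e-12)
  expect_equal(propagate_error(function(x) log10(x), 10, 1,
                               method = "derivative"),
               1 / (10 * log(10)), tolerance = 1e-6)

  # functional and Monte Carlo agree within 10% relative for a bias case
  vals <- c(0.94, 3.42e-10, 0.95, 4.77e-10, 0.98, 1.62e-9, 1.11, 1.04e-8)
  ses <- c(0.06, 0.70e-10, 0.03, 0.42e-10, 0.03, 0.29e-9, 0.07, 0.23e-8)
  f <- function(p) log10((p[1] / p[2]) * (p[4] / p[3])) -
    log10((p[5] / p[6]) * (p[8] / p[7]))
  se_f <- propagate_error(f, vals, ses, method = "functional")
  se_mc <- propagate_error(f, vals, ses, method = "montecarlo",
                           n_draws = 1e5, seed = 20)
  expect_lt(abs(se_mc - se_f) / se_f, 0.2)

  expect_error(propagate_error(function(p) log10(1 - p[1]), 0.5, 1),
               "parameter 1")
})

test_that("summary-statistic ANOVA matches the raw-data computation", {
  a0 <- anova_summary(c(1, 1), c(0.1, 0.1), c(10, 10))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  # brute-force oracle: construct raw samples with exact mean and SD, run
  # textbook ANOVA, compare
  set.seed(30)
  mk <- function(n, m, s) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  g1 <- mk(10, 0, sqrt(10) * 0.1)   # sem 0.1 with n = 10
  g2 <- mk(10, 1, sqrt(10) * 0.1)
  raw <- data.frame(y = c(g1, g2),
                    g = factor(rep(1:2, each = 10)))
  f_raw <- summary(stats::aov(y ~ g, data = raw))[[1]]$`F value`[1]
  f_sum <- anova_summary(c(mean(g1), mean(g2)),
                         c(sd(g1) / sqrt(10), sd(g2) / sqrt(10)),
                         c(10, 10))$F
  expect_equal(f_sum, f_raw, tolerance = 1e-10)

  # null calibration: ~5% rejections for three equal groups
  set.seed(31)
  rej <- vapply(1:300, function(i) {
    gs <- replicate(3, rnorm(8), simplify = FALSE)
    a <- anova_summary(vapply(gs, mean, 1),
                       vapply(gs, function(x) sd(x) / sqrt(8), 1),
                       rep(8, 3))
    a$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)

  expect_error(anova_summary(c(0, 1), c(0.1, 0.1), c(1, 10)), "n >= 2")
})

test_that("slope comparison matches the pooled-variance formula", {
  x <- 1:10
  same <- compare_linear_slopes(x, 2 * x, x, 2 * x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(32)
  y1 <- 2 * (1:20) + rnorm(20, 0, 0.1)
  y2 <- -1 * (1:20) + rnorm(20, 0, 0.1)
  r <- compare_linear_slopes(1:20, y1, 1:20, y2)

  # independent formula evaluation
  b <- function(x, y) cov(x, y) / var(x)
  rss <- function(x, y) sum((y - mean(y) - b(x, y) * (x - mean(x)))^2)
  sp2 <- (rss(1:20, y1) + rss(1:20, y2)) / (20 + 20 - 4)
  sxx <- sum((1:20 - mean(1:20))^2)
  t_oracle <- (b(1:20, y1) - b(1:20, y2)) / sqrt(sp2 * (2 / sxx))
  expect_equal(r$t, t_oracle, tolerance = 1e-10)
  expect_lt(r$p, 1e-10)

  rs <- compare_linear_slopes(1:20, y2, 1:20, y1)
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)

  expect_error(compare_linear_slopes(rep(1, 5), 1:5, 1:5, 1:5), "spread")
})
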