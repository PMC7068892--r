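test_that("percentage Bland-Altman reproduces its algebraic identities", {
  a <- c(50, 60, 71, 45.5)
  self <- bland_altman_percent(a, a)
  expect_equal(self$bias, 0)
  expect_equal(self$loa_high - self$loa_low, 0)
  # constant-ratio series: every difference is 100 * 0.1 / 1.05
  ba <- bland_altman_percent(a, 1.1 * a)
  expect_equal(ba$differences, rep(100 * 0.1 / 1.05, 4))
  expect_equal(ba$bias, 9.5238095, tolerance = 1e-7)
  expect_equal(ba$sd, 0)
  # hand-worked pair
  h <- bland_altman_percent(c(50, 60), c(55, 54))
  expect_equal(h$differences, c(100 * 5 / 52.5, 100 * (-6) / 57),
               tolerance = 1e-12)
  expect_equal(h$bias, mean(c(9.5238095, -10.5263158)), tolerance = 1e-7)
  expect_lte(h$loa_low, h$bias); expect_lte(h$bias, h$loa_high)
  # swap identity: d_i(a, b) = -d_i(b, a) exactly
  b <- c(55, 54, 80, 41)
  expect_equal(bland_altman_percent(a, b)$differences,
               -bland_altman_percent(b, a)$differences)
  expect_error(bland_altman_percent(c(1, -1), c(-1, 1)), "pair 1")
  expect_error(bland_altman_percent(1, numeric(0)), "lengths")
})

test_that("ICC(2,1) matches the ANOVA mean squares and the aov cross-check", {
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  r <- icc_single(m)
  # independent mean squares from base aov
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  expect_equal(r$msr, ms[1]); expect_equal(r$msc, ms[2])
  expect_equal(r$mse, ms[3])
  n <- nrow(m); k <- ncol(m)
  expect_equal(r$icc, (ms[1] - ms[3]) /
                 (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3])))
})

test_that("ICC limits: identical raters give 1, independent noise gives ~0", {
  x <- c(12, 15, 9, 20, 14)
  expect_equal(icc_single(cbind(x, x))$icc, 1)
  set.seed(11)
  noise <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_single(noise)$icc), 0.07)
  # invariance to shift and positive scaling
  m <- cbind(x, x + c(0.5, -0.3, 0.2, -0.1, 0.4))
  expect_equal(icc_single(m + 100)$icc, icc_single(m)$icc)
  expect_equal(icc_single(m * 3)$icc, icc_single(m)$icc)
  expect_error(icc_single(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(icc_single(matrix(1:2, 1, 2)), "at least 2")
})

test_that("ICC recovers the variance-components ratio", {
  # sigma2_subject = 4, sigma2_error = 1 -> ICC = 4 / 5
  set.seed(2024)
  subj <- rnorm(1000, 50, 2)
  m <- cbind(subj + rnorm(1000), subj + rnorm(1000))
  expect_equal(icc_single(m)$icc, 0.8, tolerance = 0.03 / 0.8)
})

test_that("Spearman correlation matches a brute-force rank oracle", {
  # ranks computed by hand: x already ranked; y = (2,1,4,3,5),
  # sum of squared rank differences = 4
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  rho_oracle <- 1 - 6 * sum((x - y)^2) / (5 * 24) # no ties
  expect_equal(rho_oracle, 0.8)
  r <- spearman_cor(x, y)
  expect_equal(r$rho, rho_oracle)
  expect_identical(r$grade, "strong")
  expect_identical(r$method, "exact permutation")
  # exact permutation p agrees with the exact distribution in cor.test
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = TRUE))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("Spearman honours monotone-transform invariance and grading bands", {
  set.seed(3)
  x <- rnorm(25); y <- x + rnorm(25, sd = 0.4)
  r0 <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, r0$rho)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, r0$rho)
  expect_equal(spearman_cor(sort(x), sort(abs(x)))$rho, 1)
  expect_equal(spearman_cor(sort(x), rev(sort(abs(x))))$rho, -1)
  expect_identical(spearman_cor(sort(x), sort(abs(x)))$grade, "very strong")
  expect_identical(spearman_cor(x, rep(1, 25))$grade, "undefined")
  expect_true(is.na(spearman_cor(x, rep(1, 25))$rho))
})

test_that("D'Agostino-Pearson K2 matches an independent implementation", {
  # frozen cross-check values computed with scipy.stats.normaltest
  r <- dagostino_k2(sin(1:50))
  expect_equal(r$statistic, 43.2676581671, tolerance = 1e-9)
  expect_equal(r$p_value, 0.0000000004, tolerance = 1e-3)
  expect_equal(r$z_skew, 0.0292431790, tolerance = 1e-9)
  expect_equal(r$z_kurt, -6.5777506036, tolerance = 1e-9)
  r2 <- dagostino_k2(exp(sin(1:40)))
  expect_equal(r2$statistic, 18.2846639589, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.0001070374, tolerance = 1e-6)
  expect_error(dagostino_k2(rnorm(19)), "n >= 20")
})

test_that("D'Agostino-Pearson has power against skewed alternatives", {
  set.seed(7)
  rej <- mean(replicate(200, dagostino_k2(rexp(200))$p_value < 0.05))
  expect_gt(rej, 0.95)
})
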