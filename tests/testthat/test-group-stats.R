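test_that("chi-square reproduces the demographic sex comparison", {
  # 7/14 vs 6/15 male/female, no continuity correction
  r <- chi_square_2x2(matrix(c(7, 14, 6, 15), 2, byrow = TRUE))
  expect_lt(abs(r$p - 0.7385), 0.0005)
  eq <- chi_square_2x2(matrix(10, 2, 2))
  expect_identical(eq$statistic, 0)
  expect_identical(eq$p, 1)
  # closed form n(ad-bc)^2 / (r1 r2 c1 c2) = 20 for the diagonal table
  d <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(d$statistic, 20)
  expect_equal(d$p, pchisq(20, 1, lower.tail = FALSE))
  expect_error(chi_square_2x2(matrix(c(1, 1, 0, 0), 2)), "empty margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("chi-square is invariant under row and column swaps", {
  m <- matrix(c(7, 14, 6, 15), 2, byrow = TRUE)
  s <- chi_square_2x2(m)$statistic
  expect_equal(chi_square_2x2(m[2:1, ])$statistic, s)
  expect_equal(chi_square_2x2(m[, 2:1])$statistic, s)
  expect_equal(chi_square_2x2(m[2:1, 2:1])$statistic, s)
})

test_that("pooled t-test reproduces the age and education comparisons", {
  age <- students_t_two_tailed(c(mean = 74.71, sd = 6.50, n = 21),
                               c(mean = 73.71, sd = 4.63, n = 21))
  expect_lt(abs(age$p - 0.5686), 0.001)
  expect_identical(age$df, 40)
  edu <- students_t_two_tailed(c(mean = 7.86, sd = 4.42, n = 21),
                               c(mean = 9.33, sd = 5.47, n = 21))
  expect_lt(abs(edu$p - 0.3476), 0.005)  # printed-summary rounding slack
  same <- students_t_two_tailed(c(mean = 1, sd = 2, n = 10),
                                c(mean = 1, sd = 2, n = 10))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(students_t_two_tailed(c(mean = 1, sd = 0, n = 5),
                                     c(mean = 2, sd = 0, n = 5)),
               "zero pooled variance")
})

test_that("raw vectors and their exact summaries give the same t", {
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(15, 2)
    b <- rnorm(12)
    raw <- students_t_two_tailed(a, b)
    summ <- students_t_two_tailed(c(mean = mean(a), sd = sd(a), n = 15),
                                  c(mean = mean(b), sd = sd(b), n = 12))
    expect_equal(raw$t, summ$t)
    expect_equal(raw$p, summ$p)
  }
})

test_that("KS gate accepts normal and rejects uniform samples", {
  ok <- vapply(1:50, function(s) {
    set.seed(s)
    ks_normality(rnorm(441))$p > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  rej <- vapply(1:20, function(s) {
    set.seed(s)
    ks_normality(runif(441) * 10)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("Wilcoxon comparison applies the Bonferroni correction", {
  a <- rep(50, 441)
  same <- wilcoxon_bonferroni(a, a, m = 20)
  expect_identical(same$p_corrected, 1)
  expect_match(same$note, "no difference")
  set.seed(2)
  base <- 50 + rnorm(441, sd = 5)
  shifted <- wilcoxon_bonferroni(base + 3, base + rnorm(441, sd = 0.5),
                                 m = 20)
  expect_lt(shifted$p_raw, 0.001)
  expect_identical(shifted$p_corrected, min(1, 20 * shifted$p_raw))
  # correction is monotone in m and capped at 1
  m5 <- wilcoxon_bonferroni(base + 0.05 * rnorm(441) + 0.02, base, m = 5)
  m50 <- wilcoxon_bonferroni(base + 0.05 * rnorm(441) + 0.02, base, m = 50)
  expect_gte(m50$p_corrected, m5$p_corrected)
  expect_lte(m50$p_corrected, 1)
})

test_that("significance stars follow the corrected-p thresholds", {
  expect_identical(eegmontage:::significance_stars(0.2), "")
  expect_identical(eegmontage:::significance_stars(0.01), "*")
  expect_identical(eegmontage:::significance_stars(5e-4), "**")
  expect_identical(eegmontage:::significance_stars(5e-5), "***")
})
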