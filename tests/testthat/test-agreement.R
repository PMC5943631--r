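test_that("Bland-Altman statistics match hand arithmetic", {
  # differences +4, -2, +6 around means that don't matter
  b <- c(120, 130, 125)
  rep <- bland_altman(data.frame(a = b + c(4, -2, 6), b = b), "systolic")
  expect_equal(rep$n, 3)
  expect_equal(rep$signed_mean_difference, 8 / 3)
  expect_equal(rep$absolute_mean_difference, 4)
  expect_equal(rep$sd_signed, sd(c(4, -2, 6)))
  expect_equal(rep$sd_absolute, sd(c(4, 2, 6)))
  expect_equal(rep$within_threshold_fraction, 1) # all |d| <= 10
  expect_equal(rep$limits_of_agreement,
               8 / 3 + c(-1.96, 1.96) * sd(c(4, -2, 6)))
})

test_that("perfect agreement gives zero differences and full validity", {
  x <- c(118, 126, 134, 120)
  rep <- bland_altman(data.frame(a = x, b = x), "diastolic")
  expect_equal(rep$signed_mean_difference, 0)
  expect_equal(rep$absolute_mean_difference, 0)
  expect_equal(rep$sd_signed, 0)
  expect_equal(rep$within_threshold_fraction, 1)
  expect_equal(rep$paired_p, 1)
  expect_error(bland_altman(data.frame(a = 1, b = 2), "systolic"),
               "at least 2")
})

test_that("absolute mean difference dominates |signed| and swap symmetry holds", {
  set.seed(61)
  for (rep_i in 1:25) {
    n <- sample(2:40, 1)
    a <- rnorm(n, 130, 15); b <- rnorm(n, 125, 15)
    r1 <- bland_altman(data.frame(a = a, b = b), "systolic")
    expect_gte(r1$absolute_mean_difference + 1e-12,
               abs(r1$signed_mean_difference))
    r2 <- bland_altman(data.frame(a = b, b = a), "systolic")
    expect_equal(r2$signed_mean_difference, -r1$signed_mean_difference)
    expect_equal(r2$absolute_mean_difference, r1$absolute_mean_difference)
    expect_equal(r2$sd_absolute, r1$sd_absolute)
    expect_equal(r2$limits_of_agreement,
                 -rev(r1$limits_of_agreement))
  }
})

test_that("paired test matches an independent t-distribution evaluation", {
  expect_equal(paired_test(rep(0, 5)), 1)
  expect_equal(paired_test(c(1, -1, 1, -1)), 1) # symmetric about 0
  expect_equal(paired_test(rep(2, 4)), 0) # zero variance, nonzero mean

  set.seed(71)
  d <- rnorm(20, 5, 1)
  tstat <- mean(d) / (sd(d) / sqrt(20))
  p_oracle <- 2 * pt(-abs(tstat), df = 19)
  expect_equal(paired_test(d), p_oracle, tolerance = 1e-6)
  # Wilcoxon alternative is exposed
  expect_equal(paired_test(d, "wilcoxon"),
               suppressWarnings(wilcox.test(d, mu = 0)$p.value))
})

test_that("a-priori validity thresholds are 10/5 mmHg, inclusive", {
  b <- rep(120, 4)
  sys_ok <- bland_altman(data.frame(a = b + c(10, -10, 3, 0.5), b = b),
                         "systolic")
  expect_equal(sys_ok$within_threshold_fraction, 1) # |d| = 10 counts
  expect_true(validity_check(sys_ok))

  dia <- bland_altman(data.frame(a = b + c(6, 1, -2, 0.5), b = b),
                      "diastolic")
  expect_equal(dia$within_threshold_fraction, 0.75)
  expect_false(validity_check(dia))
  expect_true(validity_check(dia, required_fraction = 0.75))
  expect_error(validity_check(dia, channel = "systolic"), "channel")
})

test_that("improvement metrics reproduce percentage arithmetic and invariances", {
  m <- improvement_metrics(c(10.8, 9.7), c(7.2, 5.1))
  expect_equal(m$accuracy_improvement, 100 * (10.8 - 7.2) / 10.8)
  expect_equal(m$accuracy_improvement_rounded, 33)

  # no change -> 0% on both metrics
  z <- improvement_metrics(c(8, 3), c(8, 3))
  expect_equal(z$accuracy_improvement, 0)
  expect_equal(z$variability_reduction, 0)

  # scale invariance: multiplying all pressures by c > 0 changes nothing
  set.seed(81)
  b <- rnorm(15, 130, 10)
  pre <- bland_altman(data.frame(a = b + rnorm(15, 8, 4), b = b), "systolic")
  post <- bland_altman(data.frame(a = b + rnorm(15, 2, 2), b = b), "systolic")
  m1 <- improvement_metrics(pre, post)
  pre2 <- bland_altman(data.frame(a = 2.5 * (b + (pre$difference)),
                                  b = 2.5 * b), "systolic")
  expect_equal(pre2$absolute_mean_difference,
               2.5 * pre$absolute_mean_difference)
  m2 <- improvement_metrics(c(2.5 * pre$absolute_mean_difference,
                              2.5 * pre$sd_absolute),
                            c(2.5 * post$absolute_mean_difference,
                              2.5 * post$sd_absolute))
  expect_equal(m2$accuracy_improvement, m1$accuracy_improvement)
  expect_equal(m2$variability_reduction, m1$variability_reduction)

  expect_error(improvement_metrics(c(0, 1), c(1, 1)), "> 0")
})

test_that("rounding of display percentages is half-away-from-zero", {
  expect_equal(improvement_metrics(c(100, 1), c(66.5, 1))
               $accuracy_improvement_rounded, 34)
  expect_equal(improvement_metrics(c(100, 1), c(100.5, 1))
               $accuracy_improvement_rounded, -1)
})

test_that("trend slope detects pressure-dependent attenuation", {
  b <- seq(100, 180, by = 5)
  a <- b - 0.2 * (b - 140) # attenuated above 140, inflated below
  rep <- bland_altman(data.frame(a = a, b = b), "systolic")
  expect_lt(rep$trend_slope, 0)
  d <- a - b; m <- (a + b) / 2
  expect_equal(rep$trend_slope, oracle_ols(m, d)[["slope"]], tolerance = 1e-9)
})
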