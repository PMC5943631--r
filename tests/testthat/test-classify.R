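test_that("threshold classification follows the inclusive OR rule", {
  chep <- chep_thresholds()
  r <- data.frame(systolic = c(136, 130, 119, 135, 130),
                  diastolic = c(80, 86, 70, 70, 85))
  expect_equal(classify_reading(r, chep), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  sprint <- sprint_thresholds()
  expect_equal(classify_reading(r, sprint), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_false(classify_reading(data.frame(systolic = 119, diastolic = 95),
                                sprint)) # no diastolic criterion
  expect_error(threshold_set("bad", -1), "> 0")
})

test_that("classification is monotone in pressures and thresholds", {
  set.seed(91)
  r <- data.frame(systolic = runif(50, 100, 180),
                  diastolic = runif(50, 60, 100))
  chep <- chep_thresholds()
  calls <- classify_reading(r, chep)
  raised <- r; raised$systolic <- raised$systolic + 5
  raised$diastolic <- raised$diastolic + 5
  expect_true(all(classify_reading(raised, chep) >= calls))
  higher <- threshold_set("higher", 145, 95)
  expect_lte(sum(classify_reading(r, higher)), sum(calls))
})

test_that("concordance counts match a naive counting oracle", {
  m <- c(TRUE, TRUE, FALSE, FALSE)
  ref <- c(TRUE, FALSE, TRUE, FALSE)
  tab <- concordance(m, ref)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))

  same <- c(TRUE, FALSE, TRUE)
  tab2 <- concordance(same, same)
  expect_equal(tab2$b + tab2$c, 0)

  set.seed(101)
  for (i in 1:20) {
    mc <- runif(50) < 0.5; rc <- runif(50) < 0.5
    tab <- concordance(mc, rc)
    cnt <- c(0, 0, 0, 0)
    for (j in 1:50) {
      if (rc[j] && mc[j]) cnt[1] <- cnt[1] + 1
      else if (rc[j] && !mc[j]) cnt[2] <- cnt[2] + 1
      else if (!rc[j] && mc[j]) cnt[3] <- cnt[3] + 1
      else cnt[4] <- cnt[4] + 1
    }
    expect_equal(c(tab$a, tab$b, tab$c, tab$d), cnt)
  }
  expect_error(concordance(m, ref[1:3]), "length")
})

test_that("treatment gap is b/(a+b) and complements sensitivity", {
  tab <- list(a = 8, b = 2, c = 3, d = 7)
  expect_equal(treatment_gap(tab), 0.20)
  expect_equal(sensitivity(tab), 0.80)
  expect_equal(treatment_gap(list(a = 5, b = 0, c = 1, d = 4)), 0)
  set.seed(111)
  for (i in 1:20) {
    t <- as.list(setNames(rmultinom(1, 40, c(0.3, 0.2, 0.2, 0.3))[, 1],
                          c("a", "b", "c", "d")))
    if (t$a + t$b == 0) next
    expect_equal(treatment_gap(t), 1 - sensitivity(t))
  }
  expect_error(treatment_gap(list(a = 0, b = 0, c = 5, d = 5)),
               "reference-positive")
})

test_that("one-tailed Fisher matches full hypergeometric enumeration", {
  # perfectly concordant balanced table: tail is the single observed table
  p <- fisher_exact_one_tailed(list(a = 10, b = 0, c = 0, d = 10), "greater")
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-12)

  # no association: observed table sits mid-tail
  expect_gt(fisher_exact_one_tailed(list(a = 5, b = 5, c = 5, d = 5),
                                    "greater"), 0.5)

  set.seed(121)
  for (i in 1:200) {
    total <- sample(4:60, 1)
    cnt <- rmultinom(1, total, runif(4, 0.05, 1))[, 1]
    tab <- list(a = cnt[1], b = cnt[2], c = cnt[3], d = cnt[4])
    for (alt in c("greater", "less")) {
      p <- fisher_exact_one_tailed(tab, alt)
      expect_equal(p, oracle_fisher(tab$a, tab$b, tab$c, tab$d, alt),
                   tolerance = 1e-10)
      expect_gt(p, 0); expect_lte(p, 1)
    }
  }
  # degenerate margins
  expect_equal(fisher_exact_one_tailed(list(a = 0, b = 0, c = 3, d = 4)), 1)
  expect_equal(fisher_exact_one_tailed(list(a = 2, b = 3, c = 0, d = 0)), 1)
})

test_that("one-tailed Fisher agrees with stats::fisher.test directions", {
  set.seed(131)
  for (i in 1:25) {
    cnt <- rmultinom(1, 30, c(0.3, 0.2, 0.25, 0.25))[, 1]
    tab <- list(a = cnt[1], b = cnt[2], c = cnt[3], d = cnt[4])
    m <- matrix(c(tab$a, tab$c, tab$b, tab$d), 2)
    expect_equal(fisher_exact_one_tailed(tab, "greater"),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-8)
    expect_equal(fisher_exact_one_tailed(tab, "less"),
                 fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("method comparison reports sensitivity, gap, and Fisher p per threshold", {
  set.seed(141)
  ref <- data.frame(systolic = runif(60, 110, 170),
                    diastolic = runif(60, 60, 95))
  same <- ref
  biased <- ref; biased$systolic <- biased$systolic - 12
  rep <- method_comparison(list(reference = ref, same = same, low = biased),
                           reference_method = "reference")
  expect_equal(nrow(rep), 6) # 3 methods x 2 threshold sets
  srow <- rep[rep$method == "same" & rep$threshold_set == "CHEP", ]
  expect_equal(srow$sensitivity, 1)
  expect_equal(srow$treatment_gap, 0)
  expect_equal(srow$fisher_p, 1)
  lrow <- rep[rep$method == "low" & rep$threshold_set == "SPRINT", ]
  expect_gt(lrow$treatment_gap, 0)
  expect_lt(lrow$positives, srow$n)
  expect_error(method_comparison(list(a = ref), "missing"), "not supplied")
})
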