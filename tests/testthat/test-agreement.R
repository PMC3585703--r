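test_that("confusion tables count the dichotomy pairwise-complete", {
  t1 <- confusion_table(rep(c("P", "N"), 5), rep(c("P", "N"), 5), "P")
  expect_identical(c(t1$fp, t1$fn), c(0L, 0L))
  t2 <- confusion_table(c("P", "P", "N", "N"), c("N", "N", "P", "P"), "P")
  expect_identical(
    c(t2$tp, t2$fp, t2$fn, t2$tn), c(0L, 2L, 2L, 0L)
  )
  t3 <- confusion_table(c("P", NA, "N"), c("P", "P", NA), "P")
  expect_identical(t3$n_pairs, 1L)
  expect_error(
    confusion_table(c(NA, NA), c("P", "N"), "P"), "empty comparison"
  )
  expect_error(confusion_table("P", c("P", "N"), "P"), "equal length")
})

test_that("kappa follows the marginal-product formula with its bands", {
  perfect <- confusion_table(c("P", "P", "N"), c("P", "P", "N"), "P")
  expect_equal(cohen_kappa(perfect)$kappa, 1)
  expect_identical(cohen_kappa(perfect)$band, "almost_perfect")

  t <- structure(
    list(tp = 40L, fp = 10L, fn = 5L, tn = 45L, n_pairs = 100L),
    class = "confusion_2x2"
  )
  k <- cohen_kappa(t)
  expect_equal(k$kappa, 0.70) # p_o 0.85, p_e 0.50
  expect_identical(k$band, "substantial")

  # independence-proportional margins give kappa exactly 0
  t0 <- structure(
    list(tp = 6L, fp = 14L, fn = 24L, tn = 56L, n_pairs = 100L),
    class = "confusion_2x2"
  )
  k0 <- cohen_kappa(t0)
  expect_equal(k0$kappa, 0) # p_o = p_e = 0.62 by construction
  expect_identical(k0$band, "slight")

  degen <- structure(
    list(tp = 10L, fp = 0L, fn = 0L, tn = 0L, n_pairs = 10L),
    class = "confusion_2x2"
  )
  expect_warning(kd <- cohen_kappa(degen), "undefined")
  expect_true(is.na(kd$kappa))
})

test_that("Landis-Koch bands map kappa ranges to their labels", {
  expect_identical(
    kappa_band(c(0.9, 0.75, 0.5, 0.3, 0.1, -0.2, 0.262)),
    c("almost_perfect", "substantial", "moderate", "fair", "slight",
      "poor", "fair")
  )
})

test_that("diagnostic metrics are the four ratios with NA for 0 denominators", {
  t <- structure(
    list(tp = 40L, fp = 10L, fn = 5L, tn = 45L, n_pairs = 100L),
    class = "confusion_2x2"
  )
  m <- diagnostic_metrics(t)
  expect_equal(round(unlist(m), 3),
               c(sensitivity = 0.889, specificity = 0.818,
                 ppv = 0.8, npv = 0.9))
  no_pos_calls <- structure(
    list(tp = 0L, fp = 0L, fn = 5L, tn = 45L, n_pairs = 50L),
    class = "confusion_2x2"
  )
  expect_true(is.na(diagnostic_metrics(no_pos_calls)$ppv))
  expect_false(identical(diagnostic_metrics(no_pos_calls)$ppv, 0))
})

test_that("rate chi-square matches the Pearson formula and flags degeneracy", {
  same <- rate_chi_square(30, 100, 30, 100)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  r <- rate_chi_square(30, 100, 10, 100)
  expect_equal(r$chi2, 12.5)
  expect_equal(r$p_value, pchisq(12.5, df = 1, lower.tail = FALSE))
  expect_warning(d <- rate_chi_square(0, 50, 0, 80), "degenerate")
  expect_true(is.na(d$chi2))
  expect_error(rate_chi_square(5, 0, 1, 10), "positive totals")
})

test_that("the McNemar variant works off the paired discordant cells", {
  t <- structure(
    list(tp = 40L, fp = 12L, fn = 4L, tn = 44L, n_pairs = 100L),
    class = "confusion_2x2"
  )
  got <- rate_chi_square(0, 1, 0, 1, paired = TRUE, t = t)
  ora <- mcnemar.test(matrix(c(40, 4, 12, 44), 2))
  expect_equal(got$chi2, unname(ora$statistic))
  expect_equal(got$p_value, unname(ora$p.value))
})

test_that("agreement statistics match brute-force oracles on random tables", {
  set.seed(31)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(20:300, 1), runif(4, 0.05, 1)))
    t <- structure(
      list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
           n_pairs = sum(cells)),
      class = "confusion_2x2"
    )
    ko <- kappa_oracle(cells[1], cells[2], cells[3], cells[4])
    if (is.finite(ko)) {
      expect_equal(suppressWarnings(cohen_kappa(t)$kappa), ko)
    }
    expect_equal(
      unlist(diagnostic_metrics(t)),
      metrics_oracle(cells[1], cells[2], cells[3], cells[4])
    )
  }
})

test_that("kappa agrees with an independent library implementation", {
  set.seed(41)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, 150, runif(4, 0.1, 1))) + 1L
    t <- structure(
      list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
           n_pairs = sum(cells)),
      class = "confusion_2x2"
    )
    m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2)
    expect_equal(
      cohen_kappa(t)$kappa, e1071::classAgreement(m)$kappa
    )
  }
})

test_that("kappa is transpose-symmetric and metrics swap sens with ppv", {
  set.seed(37)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, 200, runif(4, 0.05, 1)))
    t <- structure(
      list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
           n_pairs = 200L),
      class = "confusion_2x2"
    )
    tt <- structure(
      list(tp = cells[1], fp = cells[3], fn = cells[2], tn = cells[4],
           n_pairs = 200L),
      class = "confusion_2x2"
    )
    expect_equal(cohen_kappa(t)$kappa, cohen_kappa(tt)$kappa)
    expect_equal(
      diagnostic_metrics(t)$sensitivity, diagnostic_metrics(tt)$ppv
    )
  }
})

test_that("rates print to one decimal with half-up rounding", {
  expect_identical(preterm_rate(150, 1137), 13.2)
  expect_identical(preterm_rate(180, 1438), 12.5)
  expect_identical(preterm_rate(0, 50), 0)
  expect_identical(preterm_rate(1, 800), 0.1) # 0.125% rounds up
  expect_error(preterm_rate(1, 0), "positive")
  expect_identical(round_half_up(2.25, 1), 2.3)
  expect_identical(round_half_up(-2.25, 1), -2.3)
})

test_that("GA differences are signed comparator-minus-reference days", {
  expect_identical(ga_difference(280, 280), 0L)
  expect_identical(ga_difference(287, 280), 7L)
  expect_identical(ga_difference(259, 280), -21L)
})

test_that("discrepancy bands partition the integers at the stated cuts", {
  expect_identical(
    as.character(categorize_ga_difference(c(-15, -14, -8, -7, 0, 7, 8, 14, 15))),
    c("lt_m14", "m14_to_m8", "m14_to_m8", "within_7", "within_7",
      "within_7", "p8_to_p14", "p8_to_p14", "gt_p14")
  )
  cats <- categorize_ga_difference(-100:100)
  expect_false(anyNA(cats))
  expect_identical(as.integer(table(cats)),
                   c(86L, 7L, 15L, 7L, 86L))
})
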