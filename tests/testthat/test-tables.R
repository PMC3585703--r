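ref <- default_growth_reference()

test_that("a comparator identical to the reference agrees perfectly", {
  # LMP dated exactly consistently with the early ultrasound
  cohort <- make_cohort(
    make_record(id = "t1", lmp_days_before = 280, exams = list(c(84, 196))),
    make_record(id = "t2", lmp_days_before = 250, exams = list(c(84, 166)),
                weight = 2600),
    make_record(id = "t3", lmp_days_before = 296, exams = list(c(84, 212)),
                weight = 3700)
  )
  tab <- method_comparison(cohort, growth = ref, methods = "LMP")
  row <- tab[tab$method == "LMP" & tab$subset == "all", ]
  expect_equal(row$preterm_kappa, 1)
  expect_equal(row$preterm_sensitivity, 1)
  expect_equal(row$preterm_specificity, 1)
  expect_equal(row$preterm_chi2, 0)
  expect_equal(row$postterm_kappa, 1)
})

test_that("comparison rows conserve counts and outlier exclusion shrinks n", {
  sim <- simulate_cohort(sim_config(n = 400), seed = 21)
  tab <- method_comparison(sim$cohort, growth = ref)
  expect_identical(
    tab$n, tab$n_preterm + tab$n_term + tab$n_postterm
  )
  for (m in unique(tab$method)) {
    n_all <- tab$n[tab$method == m & tab$subset == "all"]
    n_ex <- tab$n[tab$method == m & tab$subset == "excluding_outliers"]
    expect_lte(n_ex, n_all)
  }
  # each comparison is restricted to pairs having both estimates
  est <- ga_estimates(sim$cohort)
  with_ref <- est$id[est$method == "US_7_20"]
  n_lmp_pairs <- length(intersect(est$id[est$method == "LMP"], with_ref))
  expect_identical(
    tab$n[tab$method == "LMP" & tab$subset == "all"], n_lmp_pairs
  )
})

test_that("stratified difference tables summarise each stratum", {
  # constant +20-day LMP-vs-US offset in every record
  cohort <- make_cohort(
    make_record(id = "s1", lmp_days_before = 300, exams = list(c(84, 196)),
                age_group = "10-19"),
    make_record(id = "s2", lmp_days_before = 290, exams = list(c(84, 186)),
                age_group = "20-34"),
    make_record(id = "s3", lmp_days_before = 295, exams = list(c(84, 191)),
                age_group = "20-34")
  )
  tab <- stratified_difference_table(cohort, "LMP", "age_group")
  expect_identical(tab$stratum, c("10-19", "20-34"))
  expect_identical(tab$n, c(1L, 2L))
  expect_equal(tab$mean_diff, c(20, 20))
  expect_equal(tab$pct_gt_p14, c(100, 100))
  expect_equal(tab$pct_within_7, c(0, 0))
})

test_that("single-stratum input yields one row and no p-value", {
  cohort <- make_record(
    id = "s4", lmp_days_before = 280, exams = list(c(84, 196))
  )
  tab <- stratified_difference_table(cohort, "LMP", "city")
  expect_identical(nrow(tab), 1L)
  expect_true(is.na(tab$p_value))
  expect_equal(tab$mean_diff, 0)
  expect_equal(tab$pct_within_7, 100)
})

test_that("a stratum with no complete pairs keeps its row with n = 0", {
  cohort <- make_cohort(
    make_record(id = "s5", lmp_days_before = 280, exams = list(c(84, 196)),
                city = "city1"),
    make_record(id = "s6", exams = list(c(84, 196)), city = "city2")
  )
  tab <- stratified_difference_table(cohort, "LMP", "city")
  expect_identical(tab$n[tab$stratum == "city2"], 0L)
  expect_true(is.na(tab$mean_diff[tab$stratum == "city2"]))
})

test_that("infant stratifiers band weight and reference GA as published", {
  sim <- simulate_cohort(sim_config(n = 300), seed = 23)
  bw <- stratified_difference_table(sim$cohort, "CAPURRO", "birth_weight")
  expect_true(all(bw$stratum %in%
                    c("<2500", "2500-3499", "3500-3999", ">=4000")))
  ga <- stratified_difference_table(sim$cohort, "CAPURRO", "ga_at_birth")
  expect_true(all(ga$stratum %in% c("<=36", "37", "38-39", "40-41", ">=42")))
  expect_error(
    stratified_difference_table(sim$cohort, "CAPURRO", "nope"),
    "unknown stratifier"
  )
})

test_that("the GA distribution table reproduces printed-count arithmetic", {
  counts <- c(9, 4, 6, 5, 16, 19, 28, 52, 128, 179, 302, 238, 111, 13, 2)
  weeks <- c(28, 30:42, 43)
  ga <- rep(weeks * 7L, counts)
  tab <- ga_distribution(ga)
  sub <- tab[tab$week_group == "preterm_subtotal", ]
  expect_identical(sub$n, 139L)
  expect_identical(sub$pct, 12.5)
  expect_identical(sum(tab$n[seq_len(which(tab$week_group == "36"))]), 139L)
  expect_identical(tab$cum_pct[tab$week_group == ">=43"], 100.0)
  expect_identical(sum(tab$n), 1112L + 139L) # subtotal row double-counts
  expect_identical(tab$n[tab$week_group == "<=29"], 9L)
})

test_that("empty estimate sets give an empty distribution table", {
  tab <- ga_distribution(integer())
  expect_identical(nrow(tab), 0L)
  expect_identical(
    names(tab), c("week_group", "n", "pct", "cum_pct")
  )
})
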