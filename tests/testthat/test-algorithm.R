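ref <- default_growth_reference()

test_that("a plausible early ultrasound is assigned first with empty trail", {
  rec <- make_record(
    id = "u1", lmp_days_before = 280,
    exams = list(c(84, 196)), capurro = 275, weight = 3400
  )
  res <- assign_ga(rec, ref = ref)
  expect_identical(res$status, "classified")
  expect_identical(res$assigned_method, "US_7_20")
  expect_identical(res$ga_days, 280L)
  expect_identical(nrow(res$exclusion_trail[[1]]), 0L)
})

test_that("an outlying top source falls through and is recorded", {
  # early exam implies 180 d (25 w) at birth: 3400 g is a gross outlier
  # under it, while the 21-28 w exam implies a plausible 280 d
  rec <- make_record(
    id = "u2", exams = list(c(84, 96), c(154, 126)), weight = 3400
  )
  res <- assign_ga(rec, ref = ref)
  expect_identical(res$assigned_method, "US_21_28")
  expect_identical(res$ga_days, 280L)
  expect_identical(
    res$exclusion_trail[[1]],
    tibble::tibble(method = "US_7_20", reason = "outlier")
  )
})

test_that("a record with no sources is unclassified with all-missing trail", {
  res <- assign_ga(make_record(id = "u3"), ref = ref)
  expect_identical(res$status, "unclassified")
  expect_true(is.na(res$ga_days))
  expect_identical(
    res$exclusion_trail[[1]]$reason, rep("missing", 4L)
  )
  expect_identical(
    res$exclusion_trail[[1]]$method,
    c("US_7_20", "US_21_28", "US_29P", "LMP")
  )
})

test_that("an undatable source appears in the trail as invalid", {
  rec <- make_record(id = "u4", lmp_days_before = 280)
  rec$us_exams[[1]] <- tibble::tibble(
    exam_date = rec$birth_date + 3, ga_days = 84L
  )
  res <- assign_ga(rec, ref = ref)
  expect_identical(res$assigned_method, "LMP")
  tr <- res$exclusion_trail[[1]]
  expect_identical(tr$reason[tr$method == "US_7_20"], "invalid")
})

test_that("conservation and priority soundness hold on simulated cohorts", {
  sim <- simulate_cohort(sim_config(n = 250), seed = 9)
  res <- assign_ga(sim$cohort, ref = ref)
  expect_identical(nrow(res), 250L)
  expect_identical(
    sum(res$status == "classified") + sum(res$status == "unclassified"), 250L
  )
  prio <- c("US_7_20", "US_21_28", "US_29P", "LMP")
  for (i in seq_len(nrow(res))) {
    skipped <- res$exclusion_trail[[i]]$method
    if (res$status[i] == "classified") {
      k <- match(res$assigned_method[i], prio)
      expect_identical(skipped, prio[seq_len(k - 1)])
    } else {
      expect_identical(skipped, prio)
    }
  }
  tally <- entrance_tally(res)
  expect_identical(sum(tally$n), 250L)
  # classified records carry a GA; unclassified never do
  expect_identical(res$status == "classified", !is.na(res$ga_days))
})

test_that("adding a plausible early ultrasound can only promote to it", {
  rec <- make_record(id = "u5", lmp_days_before = 280, weight = 3400)
  before <- assign_ga(rec, ref = ref)
  expect_identical(before$assigned_method, "LMP")
  rec$us_exams[[1]] <- tibble::tibble(
    exam_date = rec$birth_date - 196, ga_days = 84L
  )
  after <- assign_ga(rec, ref = ref)
  expect_identical(after$assigned_method, "US_7_20")
})

test_that("disabling the outlier check assigns the first available source", {
  rec <- make_record(
    id = "u6", exams = list(c(84, 96), c(154, 126)), weight = 3400
  )
  res <- assign_ga(rec, ref = NULL)
  expect_identical(res$assigned_method, "US_7_20")
  sim <- simulate_cohort(sim_config(n = 150), seed = 13)
  res <- assign_ga(sim$cohort, ref = NULL)
  em_first <- ga_estimates(sim$cohort)
  first <- vapply(
    split(as.character(em_first$method), em_first$id),
    function(m) {
      prio <- c("US_7_20", "US_21_28", "US_29P", "LMP")
      prio[min(match(m, prio), na.rm = TRUE)]
    },
    character(1)
  )
  got <- res$assigned_method[res$status == "classified"]
  names(got) <- res$id[res$status == "classified"]
  expect_identical(got[names(first)], first)
})

test_that("the Capurro exam can be appended to the priority by choice", {
  rec <- make_record(id = "u7", capurro = 270, weight = 3400)
  default <- assign_ga(rec, ref = ref)
  expect_identical(default$status, "unclassified")
  with_cap <- assign_ga(
    rec, ref = ref,
    priority = c("US_7_20", "US_21_28", "US_29P", "LMP", "CAPURRO")
  )
  expect_identical(with_cap$assigned_method, "CAPURRO")
})

test_that("the LMP criterion can be restricted to certain dates", {
  unsure <- make_record(id = "u8", lmp_days_before = 280, lmp_certain = FALSE)
  sure <- make_record(id = "u9", lmp_days_before = 280, lmp_certain = TRUE)
  cohort <- make_cohort(unsure, sure)
  res <- assign_ga(cohort, ref = ref, lmp_certain_only = TRUE)
  expect_identical(res$status, c("unclassified", "classified"))
  tr <- res$exclusion_trail[[1]]
  expect_identical(tr$reason[tr$method == "LMP"], "missing")
})

test_that("empty cohorts give empty assignments and a zero tally", {
  empty <- simulate_cohort(sim_config(n = 0), seed = 1)$cohort
  res <- assign_ga(empty, ref = ref)
  expect_identical(nrow(res), 0L)
  expect_identical(sum(entrance_tally(res)$n), 0L)
  expect_error(assign_ga(empty, ref = ref, priority = character()), "non-empty")
})
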