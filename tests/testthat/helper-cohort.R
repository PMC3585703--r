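# In-code fixtures: hand-built cohort rows and independent oracles used
# across test files.

empty_exams <- function() {
  tibble::tibble(exam_date = as.Date(character()), ga_days = integer())
}

# One cohort row with explicit sources; exams given as list(c(ga_at_exam,
# days_before_birth), ...).
make_record <- function(id = "r1", birth_date = as.Date("2008-06-01"),
                        lmp_days_before = NA, lmp_certain = NA,
                        exams = list(), capurro = NA_integer_,
                        weight = 3400, sex = "male", ...) {
  ex <- empty_exams()
  for (e in exams) {
    ex <- dplyr::bind_rows(ex, tibble::tibble(
      exam_date = birth_date - e[2], ga_days = as.integer(e[1])
    ))
  }
  covs <- list(
    city = "city1", age_group = "20-34", ethnicity = "white",
    schooling = ">=9", marital = "married", parity = "1"
  )
  covs[names(list(...))] <- list(...)
  tibble::tibble(
    id = id,
    lmp_date = if (is.na(lmp_days_before)) {
      as.Date(NA)
    } else {
      birth_date - lmp_days_before
    },
    lmp_certain = lmp_certain,
    capurro_ga_days = as.integer(capurro),
    birth_date = birth_date,
    birth_weight_g = weight,
    infant_sex = sex,
    city = covs$city, age_group = covs$age_group,
    ethnicity = covs$ethnicity, schooling = covs$schooling,
    marital = covs$marital, parity = covs$parity,
    us_exams = list(ex)
  )
}

make_cohort <- function(...) {
  dplyr::bind_rows(...)
}

# --- independent brute-force oracles -------------------------------------

# Kappa by expanding the table into paired label vectors and counting.
kappa_oracle <- function(tp, fp, fn, tn) {
  ref <- c(rep("P", tp), rep("N", fp), rep("P", fn), rep("N", tn))
  tst <- c(rep("P", tp), rep("P", fp), rep("N", fn), rep("N", tn))
  n <- length(ref)
  p_o <- mean(ref == tst)
  p_e <- 0
  for (lab in c("P", "N")) {
    p_e <- p_e + mean(ref == lab) * mean(tst == lab)
  }
  (p_o - p_e) / (1 - p_e)
}

metrics_oracle <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(
    sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn)
  )
}

# Pearson chi-square from the textbook formula sum (O - E)^2 / E on the
# 2x2 of group x (positive, negative).
chisq_oracle <- function(a_pos, a_total, b_pos, b_total) {
  obs <- matrix(
    c(a_pos, a_total - a_pos, b_pos, b_total - b_pos),
    nrow = 2, byrow = TRUE
  )
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - exp_)^2 / exp_)
}

# Calendar day count by enumerating dates one at a time.
day_count_oracle <- function(from, to) {
  length(seq(as.Date(from), as.Date(to), by = "1 day")) - 1L
}
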