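#' Gestational age at birth from the last menstrual period
#'
#' Menstrual dating: the GA at birth is the exact calendar day count from the
#' first day of the last menstrual period (LMP) to the date of birth.
#'
#' @param lmp_date,birth_date `Date` vectors (recycled to common length).
#'   Missing LMP dates yield `NA` (a missing source, not an error).
#' @return integer vector of GA at birth in days.
#' @export
#' @examples
#' ga_from_lmp(as.Date("2008-01-01"), as.Date("2008-10-07")) # 280
ga_from_lmp <- function(lmp_date, birth_date) {
  lmp_date <- as_iso_date(lmp_date, "lmp_date")
  birth_date <- as_iso_date(birth_date, "birth_date")
  bad <- !is.na(lmp_date) & !is.na(birth_date) & lmp_date > birth_date
  if (any(bad)) {
    abort("invalid interval: lmp_date after birth_date")
  }
  date_diff_days(birth_date, lmp_date)
}

#' Gestational age at birth from an ultrasound examination
#'
#' Ultrasound dating: days elapsed from the examination to birth, plus the
#' clinician-estimated GA in days at the time of the examination.
#'
#' @param exam_date `Date` vector of examination dates.
#' @param ga_at_exam_days non-negative integer GA at examination, in days.
#' @param birth_date `Date` vector of birth dates.
#' @return integer vector of GA at birth in days.
#' @export
#' @examples
#' ga_from_us(as.Date("2008-03-10"), 84, as.Date("2008-09-22")) # 280
ga_from_us <- function(exam_date, ga_at_exam_days, birth_date) {
  exam_date <- as_iso_date(exam_date, "exam_date")
  birth_date <- as_iso_date(birth_date, "birth_date")
  if (any(ga_at_exam_days < 0, na.rm = TRUE)) {
    abort("ga_at_exam_days must be non-negative")
  }
  bad <- !is.na(exam_date) & !is.na(birth_date) & exam_date > birth_date
  if (any(bad)) {
    abort("invalid interval: exam_date after birth_date")
  }
  date_diff_days(birth_date, exam_date) + as.integer(ga_at_exam_days)
}

#' Gestational window of an ultrasound examination
#'
#' Examinations are grouped by GA at examination into three windows using
#' completed-week semantics: 7--20 weeks is 7w0d through 20w6d (49--146 days),
#' 21--28 weeks is 147--202 days, and 29+ weeks is 203 days onward.
#' Examinations before 7 completed weeks fall outside every window.
#'
#' @param ga_at_exam_days non-negative integer vector, days.
#' @return character vector: `"US_7_20"`, `"US_21_28"`, `"US_29P"`, or
#'   `"out_of_range"`.
#' @export
us_window <- function(ga_at_exam_days) {
  if (any(ga_at_exam_days < 0, na.rm = TRUE)) {
    abort("ga_at_exam_days must be non-negative")
  }
  d <- as.integer(ga_at_exam_days)
  dplyr::case_when(
    is.na(d) ~ NA_character_,
    d < 49 ~ "out_of_range",
    d <= 146 ~ "US_7_20",
    d <= 202 ~ "US_21_28",
    TRUE ~ "US_29P"
  )
}

#' Earliest ultrasound examination within a window
#'
#' Among a pregnancy's examinations falling in the given window, selects the
#' one performed earliest in gestation (smallest GA at examination); a woman
#' scanned at 22 and again at 27 weeks contributes the 22-week scan to the
#' 21--28-week window.  Ties on GA at examination are broken by record order.
#'
#' @param exams a data frame with columns `exam_date` and `ga_days`
#'   (GA at examination, days).
#' @param window one of `"US_7_20"`, `"US_21_28"`, `"US_29P"`.
#' @return a one-row tibble, or `NULL` if no examination falls in the window.
#' @export
earliest_in_window <- function(exams, window) {
  window <- match.arg(window, GA_METHODS[1:3])
  if (is.null(exams) || nrow(exams) == 0) {
    return(NULL)
  }
  in_win <- which(us_window(exams$ga_days) == window)
  if (length(in_win) == 0) {
    return(NULL)
  }
  # which.min keeps the first index on ties: record order is the tie-break
  pick <- in_win[which.min(exams$ga_days[in_win])]
  tibble::as_tibble(exams[pick, , drop = FALSE])
}

#' Classify maturity at birth
#'
#' Completed-week convention: preterm is birth before 37 completed weeks
#' (< 259 days), post-term is 42 completed weeks or more (>= 294 days),
#' term is everything between.
#'
#' @param ga_days integer GA at birth in days (vectorized); must be >= 0.
#' @return factor with levels `preterm`, `term`, `postterm`.
#' @export
#' @examples
#' classify_maturity(c(258, 259, 293, 294))
classify_maturity <- function(ga_days) {
  if (any(ga_days < 0, na.rm = TRUE)) {
    abort("ga_days must be non-negative")
  }
  cls <- dplyr::case_when(
    is.na(ga_days) ~ NA_character_,
    ga_days < 259 ~ "preterm",
    ga_days >= 294 ~ "postterm",
    TRUE ~ "term"
  )
  factor(cls, levels = MATURITY_CLASSES)
}

#' Completed weeks from days
#'
#' @param ga_days integer days.
#' @return integer completed weeks (`floor(days / 7)`).
#' @export
ga_weeks <- function(ga_days) {
  as.integer(ga_days %/% 7L)
}

#' All available GA-at-birth estimates for a cohort
#'
#' Computes one GA-at-birth estimate per available dating source and
#' pregnancy: the earliest ultrasound in each of the three gestational
#' windows (dated by [ga_from_us()]), menstrual dating ([ga_from_lmp()]),
#' and the recorded Capurro exam value taken verbatim.  Sources that are
#' absent are simply omitted; a pregnancy with no sources contributes no
#' rows.  No pregnancy ever contributes two rows with the same method.
#'
#' @param cohort a cohort tibble (see [read_cohort()] for the schema): one
#'   row per pregnancy with at least `id`, `birth_date`, `lmp_date`,
#'   `capurro_ga_days` and a `us_exams` list-column of data frames with
#'   `exam_date` and `ga_days`.
#' @return tibble with columns `id`, `method` (factor over the five method
#'   labels), `ga_days`, `ga_weeks`.
#' @export
ga_estimates <- function(cohort) {
  stopifnot(all(c("id", "birth_date", "us_exams") %in% names(cohort)))
  per_record <- function(id, birth_date, lmp_date, exams, capurro) {
    rows <- list()
    # a source whose dates form an invalid interval is dropped, not fatal
    skip_invalid <- function(method, expr) {
      tryCatch(expr, error = function(e) {
        warn(sprintf("record %s: %s estimate dropped (%s)",
                     id, method, conditionMessage(e)))
        NULL
      })
    }
    for (w in GA_METHODS[1:3]) {
      ex <- earliest_in_window(exams, w)
      if (!is.null(ex)) {
        rows[[w]] <- skip_invalid(w, tibble::tibble(
          method = w,
          ga_days = ga_from_us(ex$exam_date, ex$ga_days, birth_date)
        ))
      }
    }
    if (!is.na(lmp_date)) {
      rows[["LMP"]] <- skip_invalid("LMP", tibble::tibble(
        method = "LMP", ga_days = ga_from_lmp(lmp_date, birth_date)
      ))
    }
    if (!is.na(capurro)) {
      rows[["CAPURRO"]] <- tibble::tibble(
        method = "CAPURRO", ga_days = as.integer(capurro)
      )
    }
    if (length(rows) == 0) {
      return(NULL)
    }
    dplyr::bind_rows(rows)
  }
  out <- purrr::pmap(
    list(
      cohort$id, as.list(cohort$birth_date), as.list(cohort$lmp_date),
      cohort$us_exams, as.list(cohort$capurro_ga_days)
    ),
    function(id, bd, lmp, ex, cap) {
      r <- per_record(id, bd, lmp, ex, cap)
      if (is.null(r)) NULL else dplyr::mutate(r, id = id, .before = 1)
    }
  )
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      id = character(), method = character(), ga_days = integer()
    )
  }
  out$method <- factor(out$method, levels = GA_METHODS)
  out$ga_weeks <- ga_weeks(out$ga_days)
  out
}
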