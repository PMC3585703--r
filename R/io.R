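COHORT_SCHEMA <- "gestage-cohort-v1"

# Fixed (non-exam) columns of the cohort CSV, in file order.
COHORT_FIXED_COLS <- c(
  "id", "lmp_date", "lmp_certain", "capurro_ga_days", "birth_date",
  "birth_weight_g", "sex", "city", "age_group", "ethnicity", "schooling",
  "marital", "parity"
)

#' Write a cohort CSV
#'
#' One row per pregnancy in a wide layout: the fixed columns (`id`,
#' `lmp_date`, `lmp_certain` as 0/1/blank, `capurro_ga_days`, `birth_date`,
#' `birth_weight_g`, `sex`, six maternal covariates) followed by
#' `us1_date,us1_ga_days,...,usK_date,usK_ga_days` ultrasound pairs.  Dates
#' are ISO-8601.  The first line is a schema-version comment
#' (`#gestage-cohort-v1`); [read_cohort()] refuses files without it.
#'
#' @param cohort a cohort tibble.
#' @param path output file.
#' @param k number of ultrasound slots; defaults to the cohort's maximum.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, k = NULL) {
  n_exams <- purrr::map_int(
    cohort$us_exams, function(ex) if (is.null(ex)) 0L else nrow(ex)
  )
  if (is.null(k)) {
    k <- max(c(n_exams, 1L))
  }
  if (any(n_exams > k)) {
    abort(sprintf("k = %d is too small: a record has %d exams", k, max(n_exams)))
  }
  out <- tibble::tibble(
    id = cohort$id,
    lmp_date = format(cohort$lmp_date, "%Y-%m-%d"),
    lmp_certain = ifelse(is.na(cohort$lmp_certain), NA_integer_,
                         as.integer(cohort$lmp_certain)),
    capurro_ga_days = cohort$capurro_ga_days,
    birth_date = format(cohort$birth_date, "%Y-%m-%d"),
    birth_weight_g = cohort$birth_weight_g,
    sex = cohort$infant_sex,
    city = cohort$city, age_group = cohort$age_group,
    ethnicity = cohort$ethnicity, schooling = cohort$schooling,
    marital = cohort$marital, parity = cohort$parity
  )
  for (j in seq_len(k)) {
    out[[sprintf("us%d_date", j)]] <- purrr::map_chr(
      cohort$us_exams,
      function(ex) {
        if (is.null(ex) || nrow(ex) < j) {
          NA_character_
        } else {
          format(ex$exam_date[j], "%Y-%m-%d")
        }
      }
    )
    out[[sprintf("us%d_ga_days", j)]] <- purrr::map_int(
      cohort$us_exams,
      function(ex) if (is.null(ex) || nrow(ex) < j) NA_integer_ else ex$ga_days[j]
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", COHORT_SCHEMA), con)
  utils::write.csv(as.data.frame(out), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Parses the wide cohort schema written by [write_cohort()].  Well-formed
#' rows become cohort records; malformed rows (unparseable or missing birth
#' date, non-positive birth weight, an exam dated after birth, a duplicate
#' id, out-of-range exam GA) are skipped and logged individually.
#'
#' @param path input file; its first line must declare a supported schema
#'   version, otherwise reading fails outright.
#' @return list with `cohort` (tibble) and `issues` (tibble `row`, `id`,
#'   `reason`, one entry per skipped row).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path))
  }
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("#", COHORT_SCHEMA))) {
    abort(sprintf(
      "unknown cohort schema: expected first line '#%s'", COHORT_SCHEMA
    ))
  }
  raw <- utils::read.csv(
    path, skip = 1, colClasses = "character", check.names = FALSE
  )
  missing_cols <- setdiff(COHORT_FIXED_COLS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cohort file lacks columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  us_idx <- sort(as.integer(sub(
    "^us(\\d+)_date$", "\\1",
    grep("^us\\d+_date$", names(raw), value = TRUE)
  )))

  issues <- list()
  records <- vector("list", nrow(raw))
  seen_ids <- character()
  blank <- function(x) is.na(x) | x == ""
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    rec <- tryCatch(
      {
        if (blank(row$id)) {
          abort("missing id")
        }
        if (row$id %in% seen_ids) {
          abort("duplicate id")
        }
        if (blank(row$birth_date)) {
          abort("missing birth_date")
        }
        birth_date <- as_iso_date(row$birth_date, "birth_date")
        weight <- as.numeric(row$birth_weight_g)
        if (is.na(weight) || weight <= 0) {
          abort("birth_weight_g must be positive")
        }
        if (!row$sex %in% c("male", "female")) {
          abort("sex must be 'male' or 'female'")
        }
        exams <- tibble::tibble(
          exam_date = as.Date(character()), ga_days = integer()
        )
        for (j in us_idx) {
          d <- row[[sprintf("us%d_date", j)]]
          g <- row[[sprintf("us%d_ga_days", j)]]
          if (blank(d) && blank(g)) {
            next
          }
          if (blank(d) || blank(g)) {
            abort(sprintf("us%d exam has date or ga_days but not both", j))
          }
          ed <- as_iso_date(d, sprintf("us%d_date", j))
          gd <- suppressWarnings(as.integer(g))
          if (is.na(gd) || gd < 0 || gd > 315) {
            abort(sprintf("us%d_ga_days outside 0..315", j))
          }
          if (ed > birth_date) {
            abort(sprintf("us%d_date after birth_date", j))
          }
          exams <- dplyr::bind_rows(
            exams, tibble::tibble(exam_date = ed, ga_days = gd)
          )
        }
        lmp_date <- if (blank(row$lmp_date)) {
          as.Date(NA)
        } else {
          as_iso_date(row$lmp_date, "lmp_date")
        }
        if (!is.na(lmp_date) && lmp_date > birth_date) {
          abort("lmp_date after birth_date")
        }
        lmp_certain <- if (blank(row$lmp_certain)) {
          NA
        } else if (row$lmp_certain %in% c("0", "1")) {
          row$lmp_certain == "1"
        } else {
          abort("lmp_certain must be 0, 1 or blank")
        }
        capurro <- if (blank(row$capurro_ga_days)) {
          NA_integer_
        } else {
          cg <- suppressWarnings(as.integer(row$capurro_ga_days))
          if (is.na(cg) || cg < 0) {
            abort("capurro_ga_days must be a non-negative integer")
          }
          cg
        }
        tibble::tibble(
          id = row$id, lmp_date = lmp_date, lmp_certain = lmp_certain,
          capurro_ga_days = capurro, birth_date = birth_date,
          birth_weight_g = weight, infant_sex = row$sex,
          city = row$city, age_group = row$age_group,
          ethnicity = row$ethnicity, schooling = row$schooling,
          marital = row$marital, parity = row$parity,
          us_exams = list(exams)
        )
      },
      error = function(e) {
        rid <- if (blank(row$id)) NA_character_ else row$id
        issues[[length(issues) + 1]] <<- tibble::tibble(
          row = i, id = rid, reason = conditionMessage(e)
        )
        NULL
      }
    )
    if (!is.null(rec)) {
      seen_ids <- c(seen_ids, rec$id)
      records[[i]] <- rec
    }
  }
  cohort <- dplyr::bind_rows(records)
  if (nrow(cohort) == 0) {
    cohort <- simulate_cohort(sim_config(n = 0), seed = 1)$cohort
  }
  issues <- if (length(issues) == 0) {
    tibble::tibble(row = integer(), id = character(), reason = character())
  } else {
    dplyr::bind_rows(issues)
  }
  list(cohort = cohort, issues = issues)
}

#' Write / read the simulation truth table
#'
#' Companion CSV to a simulated cohort: `id,true_ga_days,true_class`.
#'
#' @param truth truth tibble from [simulate_cohort()].
#' @param path file path.
#' @return the truth tibble (read) or `path` invisibly (write).
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      true_ga_days = readr::col_integer(),
      true_class = readr::col_character()
    ),
    progress = FALSE
  )
}
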