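# Z-scores without the week-clamping warning: during assignment a grossly
# wrong candidate GA routinely falls outside the reference weeks, and the
# clamped Z is exactly what should flag it as an outlier.
zscores_quiet <- function(weight_g, ga_days, sex, ref) {
  withCallingHandlers(
    bw_zscore(weight_g, ga_days, sex, ref)$z,
    warning = function(w) {
      if (grepl("clamped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Hierarchical assignment of best GA at birth
#'
#' Walks an ordered priority of dating sources (by default the three
#' ultrasound windows earliest-first, then menstrual dating; the Capurro
#' exam is excluded by default) and assigns each newborn the first available
#' estimate under which its birthweight-for-GA Z-score is not an excluded
#' outlier.  The outlier check is re-evaluated per candidate estimate — the
#' same birthweight can be implausible under one source's GA and plausible
#' under another's — so an outlying top source falls through to the next
#' criterion rather than excluding the newborn outright.  A newborn with no
#' sources, or outlying under every available source, is left unclassified.
#'
#' @param cohort a cohort tibble (see [read_cohort()]).
#' @param ref a [growth_reference()] used for the outlier check; `NULL`
#'   disables outlier checking (first available source wins).
#' @param priority ordered character vector of method labels to walk.
#' @param strict logical, passed to [is_outlier()].
#' @param lmp_certain_only logical; if `TRUE` the LMP criterion only admits
#'   records whose LMP date was reported as certain.
#' @return tibble with one row per cohort record: `id`, `status`
#'   (`"classified"`/`"unclassified"`), `assigned_method`, `ga_days`,
#'   `ga_weeks`, and `exclusion_trail`, a list-column of tibbles
#'   `(method, reason)` recording every higher-priority source skipped with
#'   reason `missing`, `outlier` or `invalid`.
#' @export
assign_ga <- function(cohort, ref = default_growth_reference(),
                      priority = c("US_7_20", "US_21_28", "US_29P", "LMP"),
                      strict = FALSE, lmp_certain_only = FALSE) {
  if (length(priority) == 0) {
    abort("priority must be non-empty")
  }
  if (!all(priority %in% GA_METHODS)) {
    abort("unknown method label in priority")
  }
  n <- nrow(cohort)
  empty_trail <- tibble::tibble(method = character(), reason = character())
  if (n == 0) {
    return(tibble::tibble(
      id = character(), status = character(), assigned_method = character(),
      ga_days = integer(), ga_weeks = integer(), exclusion_trail = list()
    ))
  }
  est <- suppressWarnings(ga_estimates(cohort))
  if (lmp_certain_only) {
    certain <- cohort$id[!is.na(cohort$lmp_certain) & cohort$lmp_certain]
    est <- est[!(est$method == "LMP" & !est$id %in% certain), ]
  }

  # per-method GA vector aligned to the cohort, plus availability of the raw
  # source (present-but-undatable intervals are reported as `invalid`)
  ga_by_method <- list()
  out_by_method <- list()
  present_by_method <- list()
  for (m in priority) {
    ga_m <- est$ga_days[match(
      paste(cohort$id, m),
      paste(est$id, est$method)
    )]
    present <- switch(m,
      LMP = !is.na(cohort$lmp_date),
      CAPURRO = !is.na(cohort$capurro_ga_days),
      purrr::map_lgl(cohort$us_exams, function(ex) {
        !is.null(ex) && nrow(ex) > 0 && any(us_window(ex$ga_days) == m)
      })
    )
    if (lmp_certain_only && m == "LMP") {
      present <- present & !is.na(cohort$lmp_certain) & cohort$lmp_certain
    }
    out_m <- rep(NA, n)
    idx <- which(!is.na(ga_m))
    if (length(idx) > 0 && !is.null(ref)) {
      z <- zscores_quiet(
        cohort$birth_weight_g[idx], ga_m[idx], cohort$infant_sex[idx], ref
      )
      out_m[idx] <- is_outlier(z, strict = strict)
    } else if (length(idx) > 0) {
      out_m[idx] <- FALSE
    }
    ga_by_method[[m]] <- ga_m
    out_by_method[[m]] <- out_m
    present_by_method[[m]] <- present
  }

  results <- purrr::map(seq_len(n), function(i) {
    trail <- empty_trail
    for (m in priority) {
      ga_m <- ga_by_method[[m]][i]
      if (is.na(ga_m)) {
        reason <- if (present_by_method[[m]][i]) "invalid" else "missing"
        trail <- dplyr::bind_rows(
          trail, tibble::tibble(method = m, reason = reason)
        )
        next
      }
      if (isTRUE(out_by_method[[m]][i])) {
        trail <- dplyr::bind_rows(
          trail, tibble::tibble(method = m, reason = "outlier")
        )
        next
      }
      return(list(
        status = "classified", assigned_method = m,
        ga_days = as.integer(ga_m), trail = trail
      ))
    }
    list(
      status = "unclassified", assigned_method = NA_character_,
      ga_days = NA_integer_, trail = trail
    )
  })

  tibble::tibble(
    id = cohort$id,
    status = purrr::map_chr(results, "status"),
    assigned_method = purrr::map_chr(results, "assigned_method"),
    ga_days = purrr::map_int(results, "ga_days"),
    ga_weeks = ga_weeks(purrr::map_int(results, "ga_days")),
    exclusion_trail = purrr::map(results, "trail")
  )
}

#' Entrance-criterion tally for an assigned cohort
#'
#' Counts how many newborns entered the algorithm via each criterion (dating
#' source) plus the unclassified remainder; counts always sum to the cohort
#' size, and percents are of the cohort.
#'
#' @param assignments output of [assign_ga()].
#' @param priority the priority used (orders the rows).
#' @return tibble `criterion`, `n`, `pct` (percent of cohort, one decimal).
#' @export
entrance_tally <- function(assignments,
                           priority = c("US_7_20", "US_21_28", "US_29P", "LMP")) {
  n_total <- nrow(assignments)
  lv <- c(priority, "unclassified")
  crit <- ifelse(
    assignments$status == "classified",
    assignments$assigned_method, "unclassified"
  )
  counts <- table(factor(crit, levels = lv))
  tibble::tibble(
    criterion = lv,
    n = as.integer(counts),
    pct = if (n_total > 0) {
      round_half_up(100 * as.integer(counts) / n_total, 1)
    } else {
      rep(NA_real_, length(lv))
    }
  )
}
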