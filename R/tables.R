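# Wide (id x method) GA estimates joined with birthweight Z flags under each
# method's candidate GA; the shared backbone of the report tables.
estimate_matrix <- function(cohort, ref = NULL, strict = FALSE) {
  est <- suppressWarnings(ga_estimates(cohort))
  wide <- tidyr::pivot_wider(
    est[c("id", "method", "ga_days")],
    names_from = "method", values_from = "ga_days"
  )
  for (m in setdiff(GA_METHODS, names(wide))) {
    wide[[m]] <- NA_integer_
  }
  wide <- dplyr::left_join(
    tibble::tibble(
      id = cohort$id,
      birth_weight_g = cohort$birth_weight_g,
      infant_sex = cohort$infant_sex
    ),
    wide,
    by = "id"
  )
  if (!is.null(ref)) {
    for (m in GA_METHODS) {
      flag <- rep(NA, nrow(wide))
      idx <- which(!is.na(wide[[m]]))
      if (length(idx) > 0) {
        z <- zscores_quiet(
          wide$birth_weight_g[idx], wide[[m]][idx], wide$infant_sex[idx], ref
        )
        flag[idx] <- is_outlier(z, strict = strict)
      }
      wide[[paste0("outlier_", m)]] <- flag
    }
  }
  wide
}

# Class counts and printed percents for a vector of GA estimates.
class_counts <- function(ga_days) {
  cls <- classify_maturity(ga_days)
  counts <- table(cls)
  n <- sum(counts)
  tibble::tibble(
    n = n,
    n_preterm = as.integer(counts[["preterm"]]),
    pct_preterm = preterm_rate(counts[["preterm"]], n),
    n_term = as.integer(counts[["term"]]),
    pct_term = preterm_rate(counts[["term"]], n),
    n_postterm = as.integer(counts[["postterm"]]),
    pct_postterm = preterm_rate(counts[["postterm"]], n)
  )
}

#' Method-vs-reference comparison report
#'
#' For each comparator dating method, restricted to pregnancies having both
#' the comparator and the reference estimate, tabulates preterm / term /
#' post-term counts and percents, and — for each of the two dichotomies
#' (preterm vs not; post-term vs not) — the chi-square rate comparison,
#' Cohen's kappa with its Landis-Koch band, sensitivity, specificity, PPV
#' and NPV against the reference.  Each comparison is reported twice: on
#' all pairs, and excluding pairs where the birthweight-for-GA Z-score is
#' an outlier under either method's candidate GA.  The reference method
#' itself is reported (counts only) on every pregnancy that has it.
#'
#' @param cohort a cohort tibble.
#' @param growth a [growth_reference()] for outlier flagging.
#' @param reference reference method label (default `"US_7_20"`, the
#'   earliest-window ultrasound).
#' @param methods comparator method labels.
#' @param strict strict outlier boundary, see [is_outlier()].
#' @param paired logical; use McNemar's paired test instead of the unpaired
#'   Pearson chi-square.
#' @return tibble, one row per method x subset (`"all"` /
#'   `"excluding_outliers"`), with count columns and `preterm_*` /
#'   `postterm_*` statistic columns.
#' @export
method_comparison <- function(cohort, growth = default_growth_reference(),
                              reference = "US_7_20",
                              methods = setdiff(GA_METHODS, reference),
                              strict = FALSE, paired = FALSE) {
  stopifnot(reference %in% GA_METHODS, all(methods %in% GA_METHODS))
  em <- estimate_matrix(cohort, ref = growth, strict = strict)

  one_row <- function(label, ga_comp, ga_ref, subset) {
    cc <- class_counts(ga_comp)
    row <- dplyr::bind_cols(
      tibble::tibble(method = label, subset = subset), cc
    )
    if (is.null(ga_ref)) {
      return(row)
    }
    ref_cls <- classify_maturity(ga_ref)
    comp_cls <- classify_maturity(ga_comp)
    ref_cc <- class_counts(ga_ref)
    for (pos in c("preterm", "postterm")) {
      t2 <- confusion_table(ref_cls, comp_cls, positive = pos)
      kap <- cohen_kappa(t2)
      met <- diagnostic_metrics(t2)
      n_pos_ref <- if (pos == "preterm") ref_cc$n_preterm else ref_cc$n_postterm
      n_pos_comp <- if (pos == "preterm") cc$n_preterm else cc$n_postterm
      chi <- rate_chi_square(
        n_pos_comp, cc$n, n_pos_ref, ref_cc$n,
        paired = paired, t = t2
      )
      stats <- tibble::tibble(
        chi2 = chi$chi2, p_value = chi$p_value,
        kappa = kap$kappa, kappa_band = kap$band,
        sensitivity = met$sensitivity, specificity = met$specificity,
        ppv = met$ppv, npv = met$npv
      )
      names(stats) <- paste(pos, names(stats), sep = "_")
      row <- dplyr::bind_cols(row, stats)
    }
    row
  }

  rows <- list()
  ref_ga <- em[[reference]]
  ref_out <- em[[paste0("outlier_", reference)]]
  has_ref <- !is.na(ref_ga)
  if (!any(has_ref)) {
    abort(sprintf("no records carry the reference estimate (%s)", reference))
  }
  rows[[length(rows) + 1]] <- one_row(reference, ref_ga[has_ref], NULL, "all")
  keep_ref <- has_ref & !ref_out
  if (any(keep_ref)) {
    rows[[length(rows) + 1]] <- one_row(
      reference, ref_ga[keep_ref], NULL, "excluding_outliers"
    )
  }
  for (m in methods) {
    comp_ga <- em[[m]]
    comp_out <- em[[paste0("outlier_", m)]]
    both <- has_ref & !is.na(comp_ga)
    if (!any(both)) {
      next
    }
    rows[[length(rows) + 1]] <- one_row(
      m, comp_ga[both], ref_ga[both], "all"
    )
    keep <- both & !ref_out & !comp_out
    if (any(keep)) {
      rows[[length(rows) + 1]] <- one_row(
        m, comp_ga[keep], ref_ga[keep], "excluding_outliers"
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Derived stratifiers for the difference table, alongside the maternal
# covariate columns that can be used directly.
derived_stratum <- function(cohort, em, stratifier, reference) {
  if (stratifier %in% names(cohort)) {
    return(as.character(cohort[[stratifier]][match(em$id, cohort$id)]))
  }
  if (stratifier == "birth_weight") {
    w <- em$birth_weight_g
    return(dplyr::case_when(
      w < 2500 ~ "<2500", w < 3500 ~ "2500-3499",
      w < 4000 ~ "3500-3999", TRUE ~ ">=4000"
    ))
  }
  if (stratifier == "ga_at_birth") {
    wk <- ga_weeks(em[[reference]])
    return(dplyr::case_when(
      is.na(wk) ~ NA_character_,
      wk <= 36 ~ "<=36", wk == 37 ~ "37", wk <= 39 ~ "38-39",
      wk <= 41 ~ "40-41", TRUE ~ ">=42"
    ))
  }
  abort(sprintf("unknown stratifier '%s'", stratifier))
}

#' Stratified GA-difference table
#'
#' For pregnancies having both the comparator and the reference estimate,
#' the signed day difference (comparator minus reference) is summarised
#' within strata of a covariate: n, mean and SD of the difference, and the
#' percent of pairs in each of the five discrepancy bands; strata are
#' compared with a chi-square test on the strata-by-band contingency table.
#'
#' @param cohort a cohort tibble.
#' @param comparator comparator method (`"LMP"` or `"CAPURRO"` in the
#'   classical presentation; any method label works).
#' @param stratifier either a covariate column of the cohort (`city`,
#'   `age_group`, `ethnicity`, `schooling`, `marital`, `parity`,
#'   `lmp_certain`) or one of the derived infant stratifiers
#'   `"birth_weight"` (gram bands) and `"ga_at_birth"` (completed-week
#'   bands of the reference estimate).
#' @param reference reference method label.
#' @return tibble, one row per stratum: `stratum`, `n`, `mean_diff`,
#'   `sd_diff`, `pct_*` for the five bands, and `p_value` (across-strata
#'   chi-square; `NA` with fewer than two non-empty strata).  Strata with
#'   zero pairs keep their row with `n = 0` and `NA` statistics.
#' @export
stratified_difference_table <- function(cohort, comparator = "LMP",
                                        stratifier = "age_group",
                                        reference = "US_7_20") {
  em <- estimate_matrix(cohort)
  strat <- derived_stratum(cohort, em, stratifier, reference)
  both <- !is.na(em[[comparator]]) & !is.na(em[[reference]]) & !is.na(strat)
  diff <- ga_difference(em[[comparator]][both], em[[reference]][both])
  cat <- categorize_ga_difference(diff)
  strat_kept <- strat[both]
  canonical <- list(
    birth_weight = c("<2500", "2500-3499", "3500-3999", ">=4000"),
    ga_at_birth = c("<=36", "37", "38-39", "40-41", ">=42")
  )
  levels_all <- if (stratifier %in% names(canonical)) {
    intersect(canonical[[stratifier]], unique(strat[!is.na(strat)]))
  } else {
    sort(unique(strat[!is.na(strat)]))
  }

  rows <- purrr::map(levels_all, function(s) {
    d <- diff[strat_kept == s]
    if (length(d) == 0) {
      return(tibble::tibble(
        stratum = s, n = 0L, mean_diff = NA_real_, sd_diff = NA_real_,
        !!!setNames(
          as.list(rep(NA_real_, length(DIFF_CATEGORIES))),
          paste0("pct_", DIFF_CATEGORIES)
        )
      ))
    }
    pct <- 100 * table(categorize_ga_difference(d)) / length(d)
    dplyr::bind_cols(
      tibble::tibble(
        stratum = s, n = length(d),
        mean_diff = mean(d), sd_diff = if (length(d) > 1) sd(d) else NA_real_
      ),
      tibble::as_tibble(setNames(
        as.list(round_half_up(as.numeric(pct), 1)),
        paste0("pct_", DIFF_CATEGORIES)
      ))
    )
  })
  out <- dplyr::bind_rows(rows)

  p_val <- NA_real_
  nonempty <- unique(strat_kept)
  if (length(nonempty) >= 2) {
    tab <- table(strat_kept, cat)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    res <- tryCatch(
      suppressWarnings(stats::chisq.test(tab)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      p_val <- unname(res$p.value)
    }
  }
  out$p_value <- p_val
  out
}

#' GA-at-birth distribution table
#'
#' Per completed-week distribution of GA-at-birth estimates in the layout
#' of classical comparison tables: one row for 29 weeks and below, one per
#' week 30--42, one for 43 weeks and above, with percents to one decimal
#' and a cumulative percent ending at 100.0, plus a preterm subtotal row
#' (the sum of all rows below 37 weeks) inserted after week 36.
#'
#' @param ga_days integer vector of GA-at-birth estimates in days.
#' @return tibble with columns `week_group`, `n`, `pct`, `cum_pct`; the
#'   subtotal row has `week_group = "preterm_subtotal"` and `NA` `cum_pct`.
#'   Empty input yields an empty tibble.
#' @export
ga_distribution <- function(ga_days) {
  ga_days <- ga_days[!is.na(ga_days)]
  if (length(ga_days) == 0) {
    return(tibble::tibble(
      week_group = character(), n = integer(),
      pct = numeric(), cum_pct = numeric()
    ))
  }
  wk <- ga_weeks(ga_days)
  groups <- c("<=29", as.character(30:42), ">=43")
  grp <- dplyr::case_when(
    wk <= 29 ~ "<=29", wk >= 43 ~ ">=43", TRUE ~ as.character(wk)
  )
  counts <- table(factor(grp, levels = groups))
  n_total <- sum(counts)
  pct_exact <- 100 * as.numeric(counts) / n_total
  out <- tibble::tibble(
    week_group = groups,
    n = as.integer(counts),
    pct = round_half_up(pct_exact, 1),
    cum_pct = round_half_up(cumsum(pct_exact), 1)
  )
  preterm_rows <- which(out$week_group %in% c("<=29", as.character(30:36)))
  subtotal <- tibble::tibble(
    week_group = "preterm_subtotal",
    n = sum(out$n[preterm_rows]),
    pct = round_half_up(100 * sum(out$n[preterm_rows]) / n_total, 1),
    cum_pct = NA_real_
  )
  after <- max(preterm_rows)
  dplyr::bind_rows(
    out[seq_len(after), ], subtotal,
    out[seq(after + 1, nrow(out)), ]
  )
}
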