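#' 2x2 confusion table for a dichotomous comparison
#'
#' Pairs a test method's labels against a reference method's labels on a
#' positive-vs-rest dichotomy (positive = preterm, or = post-term, per
#' analysis).  Pairs where either label is missing are dropped
#' (pairwise-complete).
#'
#' @param reference,test equal-length label vectors (character or factor).
#' @param positive the label counted as positive.
#' @return an object of class `confusion_2x2`: a list with integer counts
#'   `tp` (both positive), `fp` (test positive, reference not), `fn`
#'   (reference positive, test not), `tn`, and `n_pairs`.
#' @export
confusion_table <- function(reference, test, positive) {
  if (length(reference) != length(test)) {
    abort("reference and test must have equal length")
  }
  keep <- !is.na(reference) & !is.na(test)
  if (!any(keep)) {
    abort("empty comparison: no pairwise-complete label pairs")
  }
  rp <- as.character(reference[keep]) == positive
  tp_ <- as.character(test[keep]) == positive
  out <- list(
    tp = sum(tp_ & rp), fp = sum(tp_ & !rp),
    fn = sum(!tp_ & rp), tn = sum(!tp_ & !rp),
    n_pairs = sum(keep)
  )
  structure(out, class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat(sprintf(
    "<confusion_2x2> n=%d  tp=%d fp=%d fn=%d tn=%d\n",
    x$n_pairs, x$tp, x$fp, x$fn, x$tn
  ))
  invisible(x)
}

#' Landis-Koch interpretation band for a kappa value
#'
#' Conventional qualitative bands: 0.81--1.00 almost perfect, 0.61--0.80
#' substantial, 0.41--0.60 moderate, 0.21--0.40 fair, 0--0.20 slight,
#' below 0 poor.
#'
#' @param kappa numeric vector.
#' @return character vector of band labels.
#' @export
kappa_band <- function(kappa) {
  dplyr::case_when(
    is.na(kappa) ~ NA_character_,
    kappa > 0.80 ~ "almost_perfect",
    kappa > 0.60 ~ "substantial",
    kappa > 0.40 ~ "moderate",
    kappa > 0.20 ~ "fair",
    kappa >= 0 ~ "slight",
    TRUE ~ "poor"
  )
}

#' Unweighted Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement proportion and p_e the expected agreement under
#' independent margins (marginal-product rule).  When the margins are
#' degenerate (p_e = 1, all mass in one row and one column) kappa is
#' undefined and `NA` is returned with a warning.
#'
#' @param t a [confusion_table()].
#' @return list with `kappa` and `band` (Landis-Koch label).
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  n <- t$n_pairs
  p_o <- (t$tp + t$tn) / n
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) +
            (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (isTRUE(all.equal(p_e, 1))) {
    warn("kappa undefined: degenerate single-cell margins (p_e = 1)")
    return(list(kappa = NA_real_, band = NA_character_))
  }
  k <- (p_o - p_e) / (1 - p_e)
  list(kappa = k, band = kappa_band(k))
}

#' Diagnostic metrics for a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp) and negative predictive value tn/(tn+fn), taking the reference
#' method as truth.  A zero denominator yields `NA` (an explicit not-defined
#' marker, never 0); renderers print it as an em dash.
#'
#' @param t a [confusion_table()].
#' @return tibble with columns `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  safe_ratio <- function(num, den) {
    if (den == 0) NA_real_ else num / den
  }
  tibble::tibble(
    sensitivity = safe_ratio(t$tp, t$tp + t$fn),
    specificity = safe_ratio(t$tn, t$tn + t$fp),
    ppv = safe_ratio(t$tp, t$tp + t$fp),
    npv = safe_ratio(t$tn, t$tn + t$fn)
  )
}

#' Chi-square comparison of two methods' positive rates
#'
#' Pearson chi-square (1 df, no continuity correction) on the unpaired 2x2
#' table of method (A vs B) by class (positive vs not), the presentation
#' used in classical method-comparison tables even when the two methods
#' score the same subjects.  A paired alternative (McNemar's test on the
#' discordant pairs of a [confusion_table()]) is available via
#' `paired = TRUE`.
#'
#' @param a_pos,a_total counts for method A: positives and total.
#' @param b_pos,b_total counts for method B.
#' @param paired logical; if `TRUE`, `t` must be supplied and McNemar's
#'   test (with continuity correction) is used instead.
#' @param t a [confusion_table()] (only for `paired = TRUE`).
#' @return list with `chi2` and `p_value`; a degenerate table (an expected
#'   cell of zero, i.e. all observations in one class) yields `NA`s with a
#'   warning.
#' @export
rate_chi_square <- function(a_pos, a_total, b_pos, b_total,
                            paired = FALSE, t = NULL) {
  if (paired) {
    stopifnot(inherits(t, "confusion_2x2"))
    m <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2)
    res <- tryCatch(
      suppressWarnings(stats::mcnemar.test(m)),
      error = function(e) NULL
    )
    if (is.null(res) || is.na(res$statistic)) {
      warn("degenerate table: McNemar statistic undefined")
      return(list(chi2 = NA_real_, p_value = NA_real_))
    }
    return(list(
      chi2 = unname(res$statistic), p_value = unname(res$p.value)
    ))
  }
  m <- matrix(
    c(a_pos, a_total - a_pos, b_pos, b_total - b_pos),
    nrow = 2, byrow = TRUE
  )
  if (any(m < 0) || any(rowSums(m) == 0)) {
    abort("counts must be non-negative with positive totals")
  }
  if (any(colSums(m) == 0)) {
    warn("degenerate table: all observations in one class, chi-square undefined")
    return(list(chi2 = NA_real_, p_value = NA_real_))
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), p_value = unname(res$p.value))
}

#' Positive-class rate as a printed percent
#'
#' @param n_positive,n_total non-negative counts, `n_total > 0`.
#' @return percent to one decimal, half-up rounding (e.g. 150 of 1137 is
#'   13.2).
#' @export
preterm_rate <- function(n_positive, n_total) {
  if (any(n_total <= 0)) {
    abort("n_total must be positive")
  }
  round_half_up(100 * n_positive / n_total, 1)
}

#' Signed GA difference in days
#'
#' Comparator estimate minus reference estimate; positive values mean the
#' comparator dates the pregnancy further along (an earlier implied
#' conception date).
#'
#' @param comparator_days,reference_days integer GA-at-birth estimates, days.
#' @return signed integer vector.
#' @export
ga_difference <- function(comparator_days, reference_days) {
  as.integer(comparator_days) - as.integer(reference_days)
}

#' Discrepancy category of a GA difference
#'
#' The five clinically motivated bands: below -14 days; -14 to -8; within
#' +/-7; +8 to +14; above +14.  The bands partition all integers.
#'
#' @param days signed integer day differences.
#' @return factor with levels `lt_m14`, `m14_to_m8`, `within_7`,
#'   `p8_to_p14`, `gt_p14`.
#' @export
categorize_ga_difference <- function(days) {
  d <- as.integer(days)
  cat <- dplyr::case_when(
    is.na(d) ~ NA_character_,
    d < -14 ~ "lt_m14",
    d <= -8 ~ "m14_to_m8",
    d <= 7 ~ "within_7",
    d <= 14 ~ "p8_to_p14",
    TRUE ~ "gt_p14"
  )
  factor(cat, levels = DIFF_CATEGORIES)
}
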