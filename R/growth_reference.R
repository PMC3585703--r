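#' Construct and validate a birthweight-for-GA growth reference
#'
#' A growth reference is a sex-by-week table of birthweight means and SDs
#' used to Z-score observed birthweights at a given GA.  Validation enforces
#' strictly positive SDs, integer weeks within 22--44, no duplicate
#' (sex, week) rows, and means strictly increasing in week for each sex over
#' weeks 22--42 (intrauterine weight gain is monotone over that range; the
#' post-term tail may flatten).
#'
#' @param table data frame with columns `sex` (`"male"`/`"female"`),
#'   `week` (integer completed weeks), `mean_g`, `sd_g` (grams).
#' @return a validated `growth_reference` tibble.
#' @seealso [default_growth_reference()], [read_growth_reference()]
#' @export
growth_reference <- function(table) {
  req <- c("sex", "week", "mean_g", "sd_g")
  if (!all(req %in% names(table))) {
    abort(paste0(
      "growth reference must have columns ", paste(req, collapse = ", ")
    ))
  }
  tab <- tibble::as_tibble(table)[req]
  tab$sex <- as.character(tab$sex)
  tab$week <- as.integer(tab$week)
  problems <- character()
  bad_sex <- !tab$sex %in% c("male", "female")
  if (any(bad_sex)) {
    problems <- c(problems, sprintf(
      "rows %s: sex must be 'male' or 'female'",
      paste(which(bad_sex), collapse = ",")
    ))
  }
  bad_week <- is.na(tab$week) | tab$week < 22 | tab$week > 44
  if (any(bad_week)) {
    problems <- c(problems, sprintf(
      "rows %s: week outside 22..44",
      paste(which(bad_week), collapse = ",")
    ))
  }
  bad_sd <- !is.finite(tab$sd_g) | tab$sd_g <= 0
  if (any(bad_sd)) {
    problems <- c(problems, sprintf(
      "rows %s: sd_g must be > 0", paste(which(bad_sd), collapse = ",")
    ))
  }
  if (anyDuplicated(tab[c("sex", "week")])) {
    problems <- c(problems, "duplicate (sex, week) rows")
  }
  if (length(problems) == 0) {
    for (s in unique(tab$sex)) {
      sub <- tab[tab$sex == s & tab$week <= 42, ]
      sub <- sub[order(sub$week), ]
      if (nrow(sub) > 1 && any(diff(sub$mean_g) <= 0)) {
        problems <- c(problems, sprintf(
          "mean_g not strictly increasing over weeks 22-42 for sex %s", s
        ))
      }
    }
  }
  if (length(problems) > 0) {
    abort(c("invalid growth reference:", problems))
  }
  tab <- tab[order(tab$sex, tab$week), ]
  class(tab) <- c("growth_reference", class(tab))
  tab
}

#' Bundled synthetic growth reference
#'
#' A parametric stand-in for a published sex-specific intrauterine growth
#' curve: the median weight follows a logistic curve in completed weeks
#' (near-exponential early growth saturating at term) and the SD is a fixed
#' coefficient of variation of the mean.  It is a synthetic reference with
#' realistic magnitudes (about 3.5 kg for a term male), not a published
#' standard; analyses of real data should supply their own table via
#' [read_growth_reference()].
#'
#' @param weeks integer vector of completed weeks covered (default 22--44).
#' @param cv coefficient of variation giving `sd_g = cv * mean_g`.
#' @return a `growth_reference`.
#' @export
default_growth_reference <- function(weeks = 22:44, cv = 0.12) {
  # logistic median curve: asymptote (g), midpoint (weeks), steepness
  pars <- list(
    male   = c(asym = 4300, mid = 31.6, k = 0.205),
    female = c(asym = 4150, mid = 31.8, k = 0.205)
  )
  rows <- purrr::imap(pars, function(p, s) {
    mean_g <- p[["asym"]] / (1 + exp(-p[["k"]] * (weeks - p[["mid"]])))
    tibble::tibble(
      sex = s, week = as.integer(weeks),
      mean_g = round(mean_g), sd_g = round(cv * mean_g)
    )
  })
  growth_reference(dplyr::bind_rows(rows))
}

#' Read / write a growth reference table
#'
#' CSV schema: header `sex,week,mean_g,sd_g`; `sex` in `male`/`female`,
#' `week` integer completed weeks.  Reading validates all invariants and
#' reports every offending row; a written table reads back identically.
#'
#' @param path file path.
#' @return `read_growth_reference()` returns a validated `growth_reference`;
#'   `write_growth_reference()` returns `path` invisibly.
#' @export
read_growth_reference <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("growth reference file not found: %s", path))
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  growth_reference(tab)
}

#' @rdname read_growth_reference
#' @param ref a `growth_reference`.
#' @export
write_growth_reference <- function(ref, path) {
  stopifnot(inherits(ref, "growth_reference"))
  readr::write_csv(as.data.frame(ref), path, progress = FALSE)
  invisible(path)
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf(
    "<growth_reference> %d sexes x weeks %d-%d\n",
    length(unique(x$sex)), min(x$week), max(x$week)
  ))
  NextMethod()
}

# Look up (mean, sd) rows for vectors of sex and completed week, clamping
# weeks outside the table range to the nearest covered week (with a warning:
# the behaviour of extreme GAs is a modelling choice, not data).
lookup_reference <- function(ref, sex, week) {
  out_m <- numeric(length(sex))
  out_s <- numeric(length(sex))
  clamped <- FALSE
  for (s in unique(sex)) {
    idx <- which(sex == s)
    sub <- ref[ref$sex == s, ]
    if (nrow(sub) == 0) {
      abort(sprintf("growth reference has no rows for sex '%s'", s))
    }
    w <- week[idx]
    w_cl <- pmin(pmax(w, min(sub$week)), max(sub$week))
    clamped <- clamped || any(w_cl != w, na.rm = TRUE)
    pos <- match(w_cl, sub$week)
    if (anyNA(pos[!is.na(w_cl)])) {
      abort(sprintf("growth reference for sex '%s' has gaps in weeks", s))
    }
    out_m[idx] <- sub$mean_g[pos]
    out_s[idx] <- sub$sd_g[pos]
  }
  if (clamped) {
    warn("GA weeks outside the reference range were clamped to the nearest table row")
  }
  list(mean_g = out_m, sd_g = out_s)
}

#' Birthweight-for-GA Z-score
#'
#' Z = (observed weight - reference mean at that sex and completed GA week)
#' / reference SD.  Weeks outside the reference range are clamped to the
#' nearest covered week with a warning.  The category bands flag grossly
#' implausible weight/GA combinations: `low_outlier` for z < -3,
#' `high_outlier` for z > +3, `interior` otherwise.
#'
#' @param weight_g positive birth weight in grams (vectorized).
#' @param ga_days GA at birth in days.
#' @param sex `"male"`/`"female"`.
#' @param ref a [growth_reference()].
#' @return tibble with columns `z` and `category`.
#' @export
#' @examples
#' ref <- default_growth_reference()
#' bw_zscore(3500, 280, "male", ref)
bw_zscore <- function(weight_g, ga_days, sex, ref) {
  stopifnot(inherits(ref, "growth_reference"))
  if (any(weight_g <= 0, na.rm = TRUE)) {
    abort("weight_g must be positive")
  }
  n <- max(length(weight_g), length(ga_days), length(sex))
  weight_g <- rep_len(weight_g, n)
  ga_days <- rep_len(ga_days, n)
  sex <- rep_len(as.character(sex), n)
  row <- lookup_reference(ref, sex, ga_weeks(ga_days))
  z <- (weight_g - row$mean_g) / row$sd_g
  category <- dplyr::case_when(
    is.na(z) ~ NA_character_,
    z < -3 ~ "low_outlier",
    z > 3 ~ "high_outlier",
    TRUE ~ "interior"
  )
  tibble::tibble(
    z = z,
    category = factor(category, c("low_outlier", "interior", "high_outlier"))
  )
}

#' Birthweight-for-GA outlier exclusion rule
#'
#' Newborns whose birthweight-for-GA Z-score is at or beyond 3 SD in either
#' direction are excluded from the "excluding outliers" analyses and trigger
#' fall-through in the assignment algorithm.  The default rule is inclusive
#' (|z| >= 3); `strict = TRUE` uses |z| > 3 instead.
#'
#' @param z numeric Z-score vector.
#' @param strict logical; use the strict (exclusive) boundary.
#' @return logical vector; `NA` z gives `NA`.
#' @export
is_outlier <- function(z, strict = FALSE) {
  if (strict) abs(z) > 3 else abs(z) >= 3
}
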