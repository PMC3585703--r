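#' Round half away from zero
#'
#' Report tables print percentages to one decimal with conventional half-up
#' rounding; base `round()` rounds half to even, which would disagree with
#' printed tables at .x5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125 * 100, 1) # 12.5
#' round_half_up(2.25, 1)        # 2.3 (base round() gives 2.2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Number of days in the calendar month containing `date`.
days_in_month <- function(date) {
  date <- as.Date(date)
  first <- as.Date(format(date, "%Y-%m-01"))
  as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
}

# Coerce to Date, refusing anything that does not parse as ISO-8601.
as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    return(x)
  }
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- !is.na(x) & x != ""
  if (any(ok)) {
    parsed <- as.Date(x[ok], format = "%Y-%m-%d")
    bad <- is.na(parsed)
    if (any(bad)) {
      abort(sprintf(
        "%s not in ISO-8601 (YYYY-MM-DD) format: %s",
        what, paste(unique(x[ok][bad]), collapse = ", ")
      ))
    }
    out[ok] <- parsed
  }
  out
}

# Integer day count between two Dates (later minus earlier).
date_diff_days <- function(later, earlier) {
  as.integer(round(as.numeric(difftime(later, earlier, units = "days"))))
}
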