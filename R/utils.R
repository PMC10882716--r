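#' Round half-up
#'
#' Commercial rounding: ties on .5 always round away from zero, matching how
#' the shares in published pharmacovigilance tables are printed (base
#' [round()] uses banker's rounding).
#'
#' @param x numeric vector
#' @param digits decimal places kept
#' @return numeric vector rounded half-up to `digits`
#' @export
#' @examples
#' round_half_up(2.345, 2)  # 2.35, not 2.34
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # tiny nudge guards against values like 4.55 stored as 4.5499999...
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Percentage of a count over a denominator
#'
#' @param n numerator count(s)
#' @param total denominator count(s)
#' @param digits decimal places (default 2, as printed in report tables)
#' @return percentage(s) on the 0-100 scale, rounded half-up
#' @export
#' @examples
#' pct(8240, 181238)  # 4.55
pct <- function(n, total, digits = 2) {
  out <- rep(NA_real_, length(n))
  ok <- !is.na(total) & total > 0
  out[ok] <- round_half_up(100 * n[ok] / rep(total, length.out = length(n))[ok], digits)
  out
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7 by default), which yields fractional IQR
#' bounds on even-ish samples; the convention is configurable.
#'
#' @param x numeric vector (NAs dropped)
#' @param type quantile algorithm passed to [stats::quantile()]
#' @return a one-row tibble with `n`, `median`, `q1`, `q3` (all NA when no
#'   non-missing values are supplied)
#' @export
#' @examples
#' quantile_summary(c(1, 2, 3, 4, 5))
quantile_summary <- function(x, type = 7) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = type, names = FALSE)
  tibble::tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

# squish whitespace and uppercase; shared by drug and PT normalization
norm_ws_upper <- function(x) {
  toupper(stringr::str_squish(as.character(x)))
}

# TRUE when every non-empty value is purely digits
all_numeric_ids <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  length(x) > 0L && all(grepl("^[0-9]+$", x))
}
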