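#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves always rounded up (for
#' positive values), the convention used when reporting percentages in
#' conservation effectiveness tables. Base [round()] uses round-half-even,
#' which would print e.g. 0.5% as 0%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.5)        # 3, not 2
#' round_half_up(64.2857, 2) # 64.29
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param count Numerator count(s).
#' @param denom Denominator total(s); a zero denominator yields `NA`.
#' @param digits Decimal places (default 2, as in effectiveness tables).
#' @return Numeric percentage(s) on the 0–100 scale.
#' @export
pct <- function(count, denom, digits = 2) {
  n <- max(length(count), length(denom))
  count <- rep_len(as.numeric(count), n)
  denom <- rep_len(as.numeric(denom), n)
  out <- round_half_up(100 * count / denom, digits)
  out[denom == 0] <- NA_real_
  out
}

# stop() with call. = FALSE, sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# largest-remainder apportionment of n items over named fractions
largest_remainder <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    abort("fractions must sum to 1 (got %.12f)", sum(fractions))
  if (any(fractions < 0)) abort("fractions must be non-negative")
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
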