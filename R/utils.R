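#' Round half away from zero
#'
#' Standard "commercial" rounding: 0.5 always rounds up (for non-negative
#' input), unlike [base::round()] which rounds half to even. Used everywhere a
#' percentage is reported to a fixed number of decimals.
#'
#' @param x numeric vector, non-negative in all package uses.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(1.568 , 1) # 1.6
#' round_half_up(26.889, 1) # 26.9
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Truncate to a fixed number of decimals
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places kept.
#' @return `x` truncated (toward zero) to `digits` decimals.
#' @export
trunc_digits <- function(x, digits = 1) {
  m <- 10^digits
  trunc(x * m) / m
}

#' Format a count as a percentage of a denominator
#'
#' @param k numerator count.
#' @param n denominator count, `> 0`.
#' @param digits decimals reported.
#' @param convention `"half_up"` (default) or `"truncate"`; registries in this
#'   field print under either convention, so both are supported.
#' @return numeric percentage to `digits` decimals.
#' @export
pct_of <- function(k, n, digits = 1, convention = c("half_up", "truncate")) {
  convention <- match.arg(convention)
  stopifnot(n > 0, k >= 0)
  p <- 100 * k / n
  if (convention == "half_up") round_half_up(p, digits) else trunc_digits(p, digits)
}

#' Elapsed time in years between two dates
#'
#' Intervals are computed in days and divided by 365.25, the convention used
#' throughout for person-time.
#'
#' @param from,to `Date` vectors.
#' @return numeric years.
#' @export
years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / 365.25
}

# internal: fail with a clear message naming the offending argument
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# internal: derive a per-unit RNG seed from a master seed and an index,
# kept inside the 32-bit signed integer range
.sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}
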