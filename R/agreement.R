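#' Laboratory testing rate per 100 person-years
#'
#' Incidence-style density of laboratory testing: the number of tests divided
#' by the accumulated person-time, scaled to 100 person-years and floored to
#' an integer. Flooring (rather than rounding) is the convention used for
#' these rates; it is the only convention consistent with treating partial
#' tests per 100 py as not yet observed.
#'
#' @param n_tests non-negative integer count of tests.
#' @param person_years total follow-up time in years, `> 0`.
#' @return object of class `rate_result`: list with `n_tests`,
#'   `person_years`, `rate_per_100py` (integer) and `rate_raw`.
#' @export
#' @examples
#' testing_rate(80302, 32397)$rate_per_100py # 247
testing_rate <- function(n_tests, person_years) {
  .check(is.numeric(n_tests) && length(n_tests) == 1 && n_tests >= 0,
         "n_tests must be a single non-negative number")
  .check(is.numeric(person_years) && length(person_years) == 1 && person_years > 0,
         "person_years must be a single positive number")
  raw <- 100 * n_tests / person_years
  structure(
    list(n_tests = as.integer(n_tests), person_years = person_years,
         rate_per_100py = as.integer(floor(raw)), rate_raw = raw),
    class = "rate_result"
  )
}

#' Proportion with a bootstrap percentile confidence interval
#'
#' Point estimate `100 * k / n` (percent, rounded half-up to one decimal) with
#' a percentile bootstrap confidence interval over `B` resamples of the `n`
#' binary observations. Resampling n Bernoulli observations with replacement
#' is distributionally identical to drawing Binomial(n, k/n) counts, which is
#' how the resamples are generated.
#'
#' @param k number of "successes", `0 <= k <= n`.
#' @param n sample size, `> 0`.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @param conf confidence level (default 0.95).
#' @return object of class `proportion_ci`: list with `k`, `n`, `p_hat`,
#'   `ci_low`, `ci_high` (percent, one decimal), the unrounded `p_raw`,
#'   `ci_raw`, and `B`, `seed`, `conf`.
#' @export
#' @examples
#' proportion_ci(3878, 8007, seed = 1)$p_hat # 48.4
proportion_ci <- function(k, n, B = 1000, seed, conf = 0.95) {
  .check(is.numeric(n) && length(n) == 1 && n > 0, "n must be positive")
  .check(is.numeric(k) && length(k) == 1 && k >= 0, "k must be non-negative")
  .check(k <= n, "k must not exceed n")
  .check(!missing(seed), "seed is required")
  p <- k / n
  set.seed(as.integer(seed))
  boot_p <- stats::rbinom(B, size = n, prob = p) / n
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot_p, c(alpha, 1 - alpha)))
  structure(
    list(k = as.integer(k), n = as.integer(n),
         p_hat = round_half_up(100 * p, 1),
         ci_low = round_half_up(100 * ci[1], 1),
         ci_high = round_half_up(100 * ci[2], 1),
         p_raw = 100 * p, ci_raw = 100 * ci,
         B = as.integer(B), seed = as.integer(seed), conf = conf),
    class = "proportion_ci"
  )
}

#' Pearson product-moment correlation with a t-based p-value
#'
#' Pairwise-complete product-moment correlation; pairs where either value is
#' missing (no data available) are dropped. The two-sided p-value uses
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; `NA` pairs are removed.
#' @return list with `r`, `p_value`, `n` (complete pairs) and `band`, the
#'   correlation-size interpretation from [interpret_r()].
#' @export
pearson_r <- function(x, y) {
  .check(length(x) == length(y), "x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  .check(n >= 3, "need at least 3 complete pairs")
  .check(stats::var(x) > 0, "zero variance in x")
  .check(stats::var(y) > 0, "zero variance in y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n, band = interpret_r(r))
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement summary for two measurements of the same
#' quantity: mean difference `d = x - y`, its standard deviation, a t-based
#' 95% confidence interval for the mean difference, the limits of agreement
#' `mean(d) +/- 1.96 sd(d)`, and a two-sided one-sample t-test of mean
#' difference zero. When the differences are constant the t statistic is
#' undefined: a zero mean difference is reported with p = 1 (the test
#' statistic is identically 0), a non-zero constant difference with p = NA,
#' mirroring the convention of not computing the test when the SD is zero.
#'
#' @param x,y numeric vectors of equal length; `NA` pairs removed.
#' @param conf confidence level for the CI of the mean difference.
#' @return object of class `bland_altman`: list with `n_pairs`, `mean_diff`,
#'   `sd_diff`, `ci_mean_low`, `ci_mean_high`, `loa_low`, `loa_high`,
#'   `p_value`.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  .check(length(x) == length(y), "x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  .check(n >= 2, "need at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  se <- s / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  if (s == 0) {
    p <- if (m == 0) 1 else NA_real_
  } else {
    p <- 2 * stats::pt(-abs(m / se), df = n - 1)
  }
  structure(
    list(n_pairs = n, mean_diff = m, sd_diff = s,
         ci_mean_low = m - tq * se, ci_mean_high = m + tq * se,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         p_value = p),
    class = "bland_altman"
  )
}

# kappa from a square contingency table of counts (internal fast path,
# shared by cohen_kappa and its bootstrap)
.kappa_from_table <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  pe <- sum(pr * pc)
  if (pe >= 1) {
    # single identical category in both margins: perfectly diagonal table
    return(list(kappa = if (po == 1) 1 else NA_real_, po = po, pe = pe,
                degenerate = TRUE))
  }
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, degenerate = FALSE)
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the marginal products. The p-value is an asymptotic
#' two-sided z-test of kappa = 0 using the standard null standard error
#' (Fleiss): `SE_0 = sqrt(p_e + p_e^2 - sum_i p_i. p_.i (p_i. + p_.i)) /
#' ((1 - p_e) sqrt(n))`.
#'
#' Degenerate tables: when both margins collapse to the same single category
#' the table is perfectly diagonal and kappa is reported as 1 (agreement is
#' perfect; chance correction is undefined so `p_value` is `NA` and
#' `degenerate` is `TRUE`). When each margin holds a different single
#' category kappa is `NA` with `degenerate = TRUE`.
#'
#' @param a,b equal-length category vectors (character or factor). Pairs with
#'   `NA` in either rater are dropped before tabulation.
#' @param categories optional character vector fixing the category set and
#'   order; defaults to the union of observed levels.
#' @return object of class `kappa_result`: list with `kappa`, `p_value`,
#'   `n_pairs`, `table`, `p_o`, `p_e`, `band` (interpretation label from
#'   [interpret_kappa()]) and `degenerate`.
#' @export
#' @examples
#' tab <- matrix(c(20, 10, 5, 65), 2) # kappa = 0.625
#' a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 65))
#' b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 65))
#' cohen_kappa(a, b)$kappa
cohen_kappa <- function(a, b, categories = NULL) {
  .check(length(a) == length(b), "a and b must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- as.character(a)[keep]; b <- as.character(b)[keep]
  .check(length(a) >= 1, "no complete pairs")
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  .check(all(a %in% categories) && all(b %in% categories),
         "values outside the supplied category set")
  tab <- table(factor(a, levels = categories), factor(b, levels = categories))
  tab <- unclass(tab)
  n <- sum(tab)
  k <- .kappa_from_table(tab)
  # fewer than 2 observed categories in each margin: no chance correction is
  # identifiable; perfect diagonal still reports kappa = 1
  if (sum(rowSums(tab) > 0) < 2 && sum(colSums(tab) > 0) < 2) {
    k$degenerate <- TRUE
    k$kappa <- if (k$po == 1) 1 else NA_real_
  }
  if (k$degenerate || is.na(k$kappa)) {
    return(structure(
      list(kappa = k$kappa, p_value = NA_real_, n_pairs = n, table = tab,
           p_o = k$po, p_e = k$pe,
           band = if (is.na(k$kappa)) NA_character_ else interpret_kappa(k$kappa),
           degenerate = TRUE),
      class = "kappa_result"
    ))
  }
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  se0 <- sqrt(max(0, k$pe + k$pe^2 - sum(pr * pc * (pr + pc)))) /
    ((1 - k$pe) * sqrt(n))
  p <- if (se0 == 0) NA_real_ else 2 * stats::pnorm(-abs(k$kappa / se0))
  structure(
    list(kappa = k$kappa, p_value = p, n_pairs = n, table = tab,
         p_o = k$po, p_e = k$pe, band = interpret_kappa(k$kappa),
         degenerate = FALSE),
    class = "kappa_result"
  )
}

#' Interpretation band for a kappa coefficient
#'
#' Operational cutoffs of Viera & Garrett, implemented as upper-closed
#' half-open bins so the printed overlapping interval ends resolve
#' deterministically: `(-1, 0]` less than chance, `(0, 0.20]` slight,
#' `(0.20, 0.40]` fair, `(0.40, 0.60]` moderate, `(0.60, 0.80]` substantial,
#' `(0.80, 1]` almost perfect.
#'
#' @param k kappa value in `[-1, 1]`.
#' @return character band label.
#' @export
interpret_kappa <- function(k) {
  .check(is.numeric(k) && length(k) == 1 && !is.na(k), "k must be a number")
  .check(k >= -1 && k <= 1, "kappa must lie in [-1, 1]")
  if (k <= 0)    return("less than chance agreement")
  if (k <= 0.20) return("slight agreement")
  if (k <= 0.40) return("fair agreement")
  if (k <= 0.60) return("moderate agreement")
  if (k <= 0.80) return("substantial agreement")
  "almost perfect agreement"
}

#' Interpretation band for a correlation coefficient
#'
#' Rule-of-thumb cutoffs of Mukaka on `|r|`, implemented as lower-closed bins
#' so that `r = 0.90` falls in "very high correlation": `[0, 0.30)`
#' negligible, `[0.30, 0.50)` low, `[0.50, 0.70)` moderate, `[0.70, 0.90)`
#' high, `[0.90, 1]` very high.
#'
#' @param r correlation in `[-1, 1]`; the absolute value is banded.
#' @return character band label.
#' @export
interpret_r <- function(r) {
  .check(is.numeric(r) && length(r) == 1 && !is.na(r), "r must be a number")
  .check(r >= -1 && r <= 1, "r must lie in [-1, 1]")
  a <- abs(r)
  if (a < 0.30) return("negligible correlation")
  if (a < 0.50) return("low correlation")
  if (a < 0.70) return("moderate correlation")
  if (a < 0.90) return("high correlation")
  "very high correlation"
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%d tests over %.2f person-years: %d per 100 py\n",
              x$n_tests, x$person_years, x$rate_per_100py))
  invisible(x)
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.1f-%.1f, %d%% percentile bootstrap, B = %d)\n",
              x$k, x$n, x$p_hat, x$ci_low, x$ci_high,
              round(100 * x$conf), x$B))
  invisible(x)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman on %d pairs\n", x$n_pairs))
  cat(sprintf("  mean diff %.4f (CI %.4f to %.4f), SD %.4f\n",
              x$mean_diff, x$ci_mean_low, x$ci_mean_high, x$sd_diff))
  cat(sprintf("  limits of agreement %.4f to %.4f; p(H0: mean = 0) = %s\n",
              x$loa_low, x$loa_high,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value)))
  invisible(x)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %s on %d pairs (%s)%s\n",
              if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa),
              x$n_pairs,
              if (is.na(x$band)) "undefined" else x$band,
              if (x$degenerate) " [degenerate table]" else ""))
  invisible(x)
}
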