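# Closest-date one-to-one pairing of laboratory results from two sources.
# Cross-source comparisons of the same analyte use the result with the
# closest collection date, respecting a 30-day interval.

#' Pair dated results from two sources within a day window
#'
#' Greedy one-to-one matching of two dated series of the same analyte for
#' one patient: all cross-pairs within `window_days` are ranked by ascending
#' absolute date difference (ties broken by earlier first-series date, then
#' earlier second-series date) and accepted in order, each result used at
#' most once. The greedy rule is deterministic and near-optimal; it is not
#' guaranteed to reach the maximum number of pairs on every geometry (see
#' the vignette for the minimal counterexample).
#'
#' @param dates_a,dates_b `Date` vectors (cohort and surveillance collection
#'   dates for one patient and one analyte).
#' @param window_days inclusive window: a pair is admissible iff
#'   `|date_b - date_a| <= window_days`. Default 30.
#' @return list with `pairs` (data frame `ia`, `ib`, `delta_days` where
#'   `delta_days = dates_b[ib] - dates_a[ia]`), `unmatched_a`, `unmatched_b`
#'   (integer indices).
#' @export
#' @examples
#' a <- as.Date(c("2010-01-01", "2010-02-01"))
#' b <- as.Date(c("2010-01-10", "2010-01-25"))
#' match_dates(a, b)$pairs # (Feb 1, Jan 25, -7) and (Jan 1, Jan 10, +9)
match_dates <- function(dates_a, dates_b, window_days = 30) {
  .check(window_days > 0, "window_days must be positive")
  dates_a <- as.Date(dates_a); dates_b <- as.Date(dates_b)
  na <- length(dates_a); nb <- length(dates_b)
  empty <- data.frame(ia = integer(), ib = integer(), delta_days = integer())
  if (na == 0 || nb == 0) {
    return(list(pairs = empty, unmatched_a = seq_len(na),
                unmatched_b = seq_len(nb)))
  }
  g <- expand.grid(ia = seq_len(na), ib = seq_len(nb))
  delta <- as.integer(dates_b[g$ib] - dates_a[g$ia])
  ok <- abs(delta) <= window_days
  g <- g[ok, , drop = FALSE]
  delta <- delta[ok]
  if (!nrow(g)) {
    return(list(pairs = empty, unmatched_a = seq_len(na),
                unmatched_b = seq_len(nb)))
  }
  ord <- order(abs(delta), dates_a[g$ia], dates_b[g$ib])
  g <- g[ord, , drop = FALSE]
  delta <- delta[ord]
  used_a <- logical(na); used_b <- logical(nb)
  keep <- logical(nrow(g))
  for (r in seq_len(nrow(g))) {
    if (!used_a[g$ia[r]] && !used_b[g$ib[r]]) {
      keep[r] <- TRUE
      used_a[g$ia[r]] <- TRUE
      used_b[g$ib[r]] <- TRUE
    }
  }
  pairs <- data.frame(ia = g$ia[keep], ib = g$ib[keep],
                      delta_days = delta[keep])
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = which(!used_a),
       unmatched_b = which(!used_b))
}

#' Deduplicate same-day tests within one source
#'
#' When a source holds several tests of the same analyte on the same day for
#' a patient, only the earliest-entered record (stable input order) is kept.
#'
#' @param results data frame with a `collection_date` column, single patient
#'   and analyte, in entry order.
#' @return list with `results` (deduplicated, original order) and
#'   `n_dropped`.
#' @export
dedup_same_day <- function(results) {
  dup <- duplicated(results$collection_date)
  list(results = results[!dup, , drop = FALSE], n_dropped = sum(dup))
}

#' Match one patient's results of one analyte across the two sources
#'
#' Wraps [match_dates()] for result tables: checks the analyte is unique,
#' deduplicates same-day tests within each source, and returns matched pairs
#' carrying both sources' values.
#'
#' @param results_a,results_b data frames with columns `analyte`,
#'   `collection_date`, `value` (and optionally `lod`) for a single patient.
#' @param window_days inclusive matching window in days.
#' @return list with `pairs` (data frame `analyte`, `date_a`, `date_b`,
#'   `delta_days`, `value_a`, `value_b`, `lod_a`, `lod_b`), `unmatched_a`,
#'   `unmatched_b` (row subsets of the deduplicated inputs) and
#'   `n_dedup_dropped`.
#' @export
match_results <- function(results_a, results_b, window_days = 30) {
  analytes <- unique(c(results_a$analyte, results_b$analyte))
  .check(length(analytes) <= 1,
         "match_results: mixed analytes in one call: ",
         paste(analytes, collapse = ", "))
  da <- dedup_same_day(results_a)
  db <- dedup_same_day(results_b)
  a <- da$results; b <- db$results
  m <- match_dates(a$collection_date, b$collection_date, window_days)
  lod_a <- if ("lod" %in% names(a)) a$lod[m$pairs$ia] else NA
  lod_b <- if ("lod" %in% names(b)) b$lod[m$pairs$ib] else NA
  pairs <- data.frame(
    analyte = rep(if (length(analytes)) analytes else NA_character_,
                  nrow(m$pairs)),
    date_a = a$collection_date[m$pairs$ia],
    date_b = b$collection_date[m$pairs$ib],
    delta_days = m$pairs$delta_days,
    value_a = a$value[m$pairs$ia],
    value_b = b$value[m$pairs$ib],
    lod_a = lod_a, lod_b = lod_b,
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       unmatched_a = a[m$unmatched_a, , drop = FALSE],
       unmatched_b = b[m$unmatched_b, , drop = FALSE],
       n_dedup_dropped = da$n_dropped + db$n_dropped)
}
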