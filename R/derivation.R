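# Eligibility, censoring and per-patient biomarker derivation. "Before cART"
# is strictly before the cART start date by default; treatment-day tests
# count as on-treatment (switchable with pre_cart_inclusive).

#' Administrative censoring of a result series
#'
#' @param results result data frame with a `collection_date` column.
#' @param bound_date latest admissible collection date (inclusive).
#' @return the rows dated on or before `bound_date`.
#' @export
censor_results <- function(results, bound_date) {
  results[results$collection_date <= as.Date(bound_date), , drop = FALSE]
}

#' Censor surveillance results by the cohort's last test dates
#'
#' Surveillance results are admissible only up to
#' `min(admin_date, last cohort test date of the same analyte for that
#' patient)`: the cohort's own recording horizon bounds what the surveillance
#' registry may contribute. When the cohort recorded no test of an analyte
#' for a patient, the bound falls back to `admin_date` alone.
#'
#' @param surv_results surveillance results carrying cohort patient codes
#'   (post-linkage), columns `code`, `analyte`, `collection_date`, …
#' @param cohort_results cohort results, same layout.
#' @param admin_date administrative censoring date.
#' @return the admissible surveillance rows.
#' @export
censor_surveillance <- function(surv_results, cohort_results, admin_date) {
  admin_date <- as.Date(admin_date)
  key <- paste(surv_results$code, surv_results$analyte, sep = "\r")
  ckey <- paste(cohort_results$code, cohort_results$analyte, sep = "\r")
  last_dates <- tapply(as.numeric(cohort_results$collection_date), ckey, max)
  bound <- rep(as.numeric(admin_date), nrow(surv_results))
  hit <- match(key, names(last_dates))
  has <- !is.na(hit)
  bound[has] <- pmin(bound[has], unname(last_dates[hit[has]]))
  surv_results[as.numeric(surv_results$collection_date) <= bound, ,
               drop = FALSE]
}

#' Person-years of follow-up
#'
#' Elapsed time from cART start to the censoring bound, in days / 365.25.
#'
#' @param cart_start,censor_bound `Date` scalars or vectors; the bound must
#'   not precede the start.
#' @return numeric years (0 for same-day start and bound; such patients are
#'   flagged downstream rather than here).
#' @export
person_years <- function(cart_start, censor_bound) {
  py <- years_between(cart_start, censor_bound)
  .check(all(py >= 0), "person_years: censoring bound precedes cART start")
  py
}

#' Apply the study eligibility rules
#'
#' Patients are excluded, in order (first reason wins, each patient counted
#' once), when they have
#' (1) no linkage code with the surveillance registry,
#' (2) no laboratory result (either analyte) in the cohort during clinical
#'     follow-up (up to the administrative censoring date), or
#' (3) no laboratory result in the cohort after initiating cART.
#'
#' @param patients cohort patient table (`code`, `cart_start`, …).
#' @param link_result a `link_result` from [link_identities()].
#' @param cohort_results cohort result table (`code`, `collection_date`, …).
#' @param admin_date administrative censoring date.
#' @param convention percentage convention passed to [pct_of()].
#' @param pre_cart_inclusive if `TRUE` a treatment-day test counts as
#'   pre-cART (and so does not rescue a patient from exclusion reason 3).
#' @return list with `eligible` (code vector) and `report`, a one-row data
#'   frame: `n_enrolled`, `excluded_no_link`, `excluded_no_labs_followup`,
#'   `excluded_no_labs_post_cart`, `n_eligible` and the matching percentages
#'   (of `n_enrolled`, one decimal).
#' @export
apply_eligibility <- function(patients, link_result, cohort_results,
                              admin_date,
                              convention = c("half_up", "truncate"),
                              pre_cart_inclusive = FALSE) {
  convention <- match.arg(convention)
  admin_date <- as.Date(admin_date)
  n_enrolled <- nrow(patients)

  linked <- patients$code %in% link_result$matched$cohort_code

  res <- censor_results(cohort_results, admin_date)
  has_labs <- patients$code %in% res$code

  post_cut <- patients$cart_start[match(res$code, patients$code)]
  is_post <- if (pre_cart_inclusive) res$collection_date > post_cut
             else res$collection_date >= post_cut
  has_post <- patients$code %in% res$code[!is.na(is_post) & is_post]

  reason <- rep("eligible", n_enrolled)
  reason[!has_post] <- "no_labs_post_cart"
  reason[!has_labs] <- "no_labs_followup"
  reason[!linked] <- "no_link"

  counts <- c(no_link = sum(reason == "no_link"),
              no_labs_followup = sum(reason == "no_labs_followup"),
              no_labs_post_cart = sum(reason == "no_labs_post_cart"))
  n_eligible <- n_enrolled - sum(counts)

  report <- data.frame(
    n_enrolled = n_enrolled,
    excluded_no_link = unname(counts["no_link"]),
    excluded_no_labs_followup = unname(counts["no_labs_followup"]),
    excluded_no_labs_post_cart = unname(counts["no_labs_post_cart"]),
    n_eligible = n_eligible,
    pct_no_link = pct_of(counts["no_link"], n_enrolled, 1, convention),
    pct_no_labs_followup = pct_of(counts["no_labs_followup"], n_enrolled, 1,
                                  convention),
    pct_no_labs_post_cart = pct_of(counts["no_labs_post_cart"], n_enrolled, 1,
                                   convention),
    pct_eligible = pct_of(n_eligible, n_enrolled, 1, convention)
  )
  rownames(report) <- NULL
  list(eligible = patients$code[reason == "eligible"], report = report,
       reason = stats::setNames(reason, patients$code))
}

#' Categorize a CD4+ T-cell count
#'
#' Clinical staging bins with a half-open middle interval:
#' `< 200`, `200 |- 350` (i.e. `[200, 350)`), `>= 350` cells/mm3.
#'
#' @param v CD4 count(s), cells/mm3, non-negative.
#' @return character vector in `{"<200", "200-349", ">=350"}` (`NA` in, `NA`
#'   out).
#' @export
categorize_cd4 <- function(v) {
  .check(all(is.na(v) | v >= 0), "categorize_cd4: negative count")
  out <- rep(NA_character_, length(v))
  out[!is.na(v) & v < 200] <- "<200"
  out[!is.na(v) & v >= 200 & v < 350] <- "200-349"
  out[!is.na(v) & v >= 350] <- ">=350"
  out
}

#' Dichotomize a viral load at its assay's detection limit
#'
#' "above" iff the result was detectable at the limit in force for its assay;
#' with the package's value encoding that is `value > lod` (below-limit
#' results are recorded at the limit itself).
#'
#' @param value reported copies/ml.
#' @param lod assay lower limit of detection, copies/ml.
#' @return character vector in `{"above", "below"}` (`NA` in, `NA` out).
#' @export
dichotomize_vl <- function(value, lod) {
  .check(all(is.na(value) | is.na(lod) | lod > 0),
         "dichotomize_vl: nonpositive detection limit")
  ifelse(is.na(value) | is.na(lod), NA_character_,
         ifelse(value > lod, "above", "below"))
}

# pre-cART subset of a series
.pre_cart <- function(dates, cart_date, inclusive = FALSE) {
  if (inclusive) dates <= cart_date else dates < cart_date
}

#' Nadir CD4+ T-cell count before cART
#'
#' Minimum over tests collected strictly before the cART start date (or on it
#' when `pre_cart_inclusive`). An empty pre-cART set yields `NA` ("no data
#' available", NDA).
#'
#' @param values CD4 counts, cells/mm3.
#' @param dates collection dates.
#' @param cart_date cART start date.
#' @param pre_cart_inclusive include treatment-day tests as pre-cART.
#' @return list with `nadir` (cells/mm3 or `NA`) and `category`
#'   (`categorize_cd4(nadir)` or `NA`).
#' @export
nadir_cd4_pre_cart <- function(values, dates, cart_date,
                               pre_cart_inclusive = FALSE) {
  pre <- .pre_cart(as.Date(dates), as.Date(cart_date), pre_cart_inclusive)
  v <- values[pre & !is.na(values)]
  if (!length(v)) return(list(nadir = NA_real_, category = NA_character_))
  nad <- min(v)
  list(nadir = nad, category = categorize_cd4(nad))
}

#' Peak viral load before cART
#'
#' Maximum over detectable tests collected strictly before the cART start
#' date. Below-limit results participate qualitatively ("below") but are
#' excluded from the quantitative maximum; a patient whose pre-cART loads
#' are all below the limit gets `NA` for the quantitative peak with
#' detectability `"below"`. An empty pre-cART set yields NDA throughout.
#'
#' @param values reported copies/ml (below-limit results recorded at the
#'   limit).
#' @param lods assay detection limits, copies/ml.
#' @param dates collection dates.
#' @param cart_date cART start date.
#' @param pre_cart_inclusive include treatment-day tests as pre-cART.
#' @return list with `peak_copies`, `peak_log10` (or `NA`) and
#'   `detectability` (`"above"`, `"below"` or `NA` for NDA).
#' @export
peak_vl_pre_cart <- function(values, lods, dates, cart_date,
                             pre_cart_inclusive = FALSE) {
  pre <- .pre_cart(as.Date(dates), as.Date(cart_date), pre_cart_inclusive)
  v <- values[pre]; l <- lods[pre]
  keep <- !is.na(v)
  v <- v[keep]; l <- l[keep]
  if (!length(v)) {
    return(list(peak_copies = NA_real_, peak_log10 = NA_real_,
                detectability = NA_character_))
  }
  det <- dichotomize_vl(v, l) == "above"
  .check(all(v[det] > 0), "peak_vl_pre_cart: nonpositive detectable copies")
  if (!any(det)) {
    return(list(peak_copies = NA_real_, peak_log10 = NA_real_,
                detectability = "below"))
  }
  pk <- max(v[det])
  list(peak_copies = pk, peak_log10 = log10(pk), detectability = "above")
}

#' First n results after cART start
#'
#' Tests collected on or after the cART start date, ascending by date
#' (stable for ties), truncated to the first `n`.
#'
#' @param values result values.
#' @param dates collection dates.
#' @param cart_date cART start date.
#' @param n maximum series length (default 10).
#' @return data frame `index`, `date`, `value` with at most `n` rows.
#' @export
first_n_post_cart <- function(values, dates, cart_date, n = 10) {
  dates <- as.Date(dates)
  post <- which(dates >= as.Date(cart_date))
  ord <- post[order(dates[post])]
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(index = seq_along(ord), date = dates[ord], value = values[ord])
}

#' Derive per-patient summary biomarkers for one source
#'
#' For every eligible patient: person-years of follow-up, pre-cART nadir CD4
#' (quantitative and categorized), pre-cART peak viral load (copies, log10,
#' detectability) and the first ten post-cART CD4 counts and viral-load
#' detectability flags.
#'
#' @param patients cohort patient table restricted to, or filterable by,
#'   `eligible`.
#' @param results result table for one source, already censored, carrying
#'   cohort codes.
#' @param eligible character vector of eligible cohort codes.
#' @param admin_date administrative censoring date (person-time bound).
#' @param pre_cart_inclusive passed to the pre-cART selectors.
#' @param n_first length of the post-cART series retained (default 10).
#' @return list with `measures` (one row per eligible patient: `code`,
#'   `site`, `person_years`, `nadir_cd4`, `nadir_cd4_category`,
#'   `peak_vl_copies`, `peak_vl_log10`, `peak_vl_detectability`) and
#'   `first_series` (long data frame `code`, `analyte`, `index`, `date`,
#'   `value`, `detectable`).
#' @export
derive_measures <- function(patients, results, eligible, admin_date,
                            pre_cart_inclusive = FALSE, n_first = 10) {
  patients <- patients[patients$code %in% eligible, , drop = FALSE]
  followup_bound <- pmin(as.Date(admin_date),
                         as.Date(patients$followup_end))
  py <- person_years(patients$cart_start, followup_bound)

  res <- results[results$code %in% eligible, , drop = FALSE]
  split_res <- split(res, factor(res$code, levels = patients$code))

  rows <- vector("list", nrow(patients))
  series <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    code <- patients$code[i]
    cart <- patients$cart_start[i]
    r <- split_res[[i]]
    cd4 <- r[r$analyte == "CD4", , drop = FALSE]
    vl <- r[r$analyte == "VL", , drop = FALSE]

    nad <- nadir_cd4_pre_cart(cd4$value, cd4$collection_date, cart,
                              pre_cart_inclusive)
    pk <- peak_vl_pre_cart(vl$value, vl$lod, vl$collection_date, cart,
                           pre_cart_inclusive)

    f_cd4 <- first_n_post_cart(cd4$value, cd4$collection_date, cart, n_first)
    f_vl <- first_n_post_cart(seq_len(nrow(vl)), vl$collection_date, cart,
                              n_first)
    rows[[i]] <- data.frame(
      code = code, site = patients$site[i], person_years = py[i],
      nadir_cd4 = nad$nadir, nadir_cd4_category = nad$category,
      peak_vl_copies = pk$peak_copies, peak_vl_log10 = pk$peak_log10,
      peak_vl_detectability = pk$detectability,
      stringsAsFactors = FALSE
    )
    s_cd4 <- if (nrow(f_cd4)) data.frame(
      code = code, analyte = "CD4", index = f_cd4$index, date = f_cd4$date,
      value = f_cd4$value, detectable = NA, stringsAsFactors = FALSE) else NULL
    s_vl <- if (nrow(f_vl)) {
      vr <- vl[f_vl$value, , drop = FALSE] # f_vl$value holds row indices
      data.frame(code = code, analyte = "VL", index = f_vl$index,
                 date = f_vl$date, value = vr$value,
                 detectable = dichotomize_vl(vr$value, vr$lod) == "above",
                 stringsAsFactors = FALSE)
    } else NULL
    series[[i]] <- rbind(s_cd4, s_vl)
  }
  measures <- do.call(rbind, rows)
  rownames(measures) <- NULL
  first_series <- do.call(rbind, series[!vapply(series, is.null, logical(1))])
  if (is.null(first_series)) {
    first_series <- data.frame(code = character(), analyte = character(),
                               index = integer(), date = as.Date(character()),
                               value = numeric(), detectable = logical())
  }
  rownames(first_series) <- NULL
  list(measures = measures, first_series = first_series)
}
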