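# End-to-end orchestration: simulate (or read) -> link -> censor ->
# eligibility -> closest-date matching audit -> per-patient derivation ->
# agreement battery, with per-site stratification and "Total" rows.

#' Configuration for a validation pipeline run
#'
#' Exactly one of `sim` (a [sim_config()], data are generated) or the two
#' path pairs (`cohort_paths`, `surveillance_paths`, each
#' `list(patients =, results =)` CSV paths) must be supplied.
#'
#' @param sim optional [sim_config()].
#' @param cohort_paths,surveillance_paths optional CSV path lists.
#' @param window_days closest-date matching window (default 30).
#' @param admin_censor_date administrative censoring date; defaults to the
#'   simulator's when `sim` is given.
#' @param convention percentage convention (`"half_up"` or `"truncate"`).
#' @param B bootstrap resamples for proportion CIs (default 1000).
#' @param seed master seed for every stochastic step of the analysis.
#' @param pre_cart_inclusive treat treatment-day tests as pre-cART.
#' @param out_dir optional directory; when given, every table is written as
#'   CSV.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, cohort_paths = NULL,
                            surveillance_paths = NULL,
                            window_days = 30,
                            admin_censor_date = NULL,
                            convention = c("half_up", "truncate"),
                            B = 1000, seed = 1L,
                            pre_cart_inclusive = FALSE,
                            out_dir = NULL) {
  convention <- match.arg(convention)
  from_sim <- !is.null(sim)
  from_paths <- !is.null(cohort_paths) && !is.null(surveillance_paths)
  .check(xor(from_sim, from_paths),
         "pipeline_config: supply exactly one of sim or both path lists")
  if (from_sim) validate_sim_config(sim)
  if (is.null(admin_censor_date)) {
    .check(from_sim, "pipeline_config: admin_censor_date required with paths")
    admin_censor_date <- sim$admin_censor_date
  }
  .check(window_days > 0, "pipeline_config: window_days must be > 0")
  structure(
    list(sim = sim, cohort_paths = cohort_paths,
         surveillance_paths = surveillance_paths,
         window_days = window_days,
         admin_censor_date = as.Date(admin_censor_date),
         convention = convention, B = as.integer(B), seed = as.integer(seed),
         pre_cart_inclusive = pre_cart_inclusive, out_dir = out_dir),
    class = "pipeline_config"
  )
}

# per-site + Total testing-rate table
.rates_table <- function(measures_cohort, cohort_results, surv_results,
                         sites) {
  count_tests <- function(res, analyte, codes) {
    sum(res$analyte == analyte & res$code %in% codes)
  }
  one_row <- function(site_codes, label) {
    py <- sum(measures_cohort$person_years[
      measures_cohort$code %in% site_codes])
    row <- data.frame(site = label, n_patients = length(site_codes),
                      person_years = py, stringsAsFactors = FALSE)
    for (spec in list(c("cd4_cohort", "CD4", "c"), c("cd4_surveillance", "CD4", "s"),
                      c("vl_cohort", "VL", "c"), c("vl_surveillance", "VL", "s"))) {
      res <- if (spec[3] == "c") cohort_results else surv_results
      n <- count_tests(res, spec[2], site_codes)
      row[[paste0("n_", spec[1])]] <- n
      row[[paste0("rate_", spec[1])]] <-
        if (py > 0) testing_rate(n, py)$rate_per_100py else NA_integer_
    }
    row
  }
  site_rows <- lapply(sites, function(s)
    one_row(measures_cohort$code[measures_cohort$site == s], s))
  total <- one_row(measures_cohort$code, "Total")
  out <- rbind(do.call(rbind, site_rows), total)
  rownames(out) <- NULL
  out
}

# proportion panel (full data incl. NDA, and disconsidering NDA) for one
# categorical derived measure, per source; seeds drawn deterministically
.proportion_panel <- function(cat_cohort, cat_surv, levels_full, B, seed_base) {
  seed_i <- 0
  one_source <- function(cats, source, panel, denom_levels) {
    cats_used <- cats
    if (panel == "disconsidering_nda") cats_used <- cats[!is.na(cats)]
    n <- length(cats_used)
    out <- lapply(denom_levels, function(lv) {
      k <- if (lv == "NDA") sum(is.na(cats_used)) else
        sum(!is.na(cats_used) & cats_used == lv)
      seed_i <<- seed_i + 1
      ci <- proportion_ci(k, n, B = B, seed = .sub_seed(seed_base, seed_i))
      data.frame(source = source, panel = panel, category = lv, n = k,
                 pct = ci$p_hat, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 denominator = n, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  out <- rbind(
    one_source(cat_cohort, "cohort", "full_data", c(levels_full, "NDA")),
    one_source(cat_surv, "surveillance", "full_data", c(levels_full, "NDA")),
    one_source(cat_cohort, "cohort", "disconsidering_nda", levels_full),
    one_source(cat_surv, "surveillance", "disconsidering_nda", levels_full)
  )
  rownames(out) <- NULL
  out
}

# first-10 post-treatment descriptive table
.first_series_table <- function(series_cohort, series_surv) {
  one <- function(series, source) {
    rows <- list()
    for (idx in sort(unique(series$index[series$analyte == "CD4"]))) {
      v <- series$value[series$analyte == "CD4" & series$index == idx]
      d <- series$detectable[series$analyte == "VL" & series$index == idx]
      rows[[length(rows) + 1]] <- data.frame(
        source = source, count_index = idx,
        cd4_n = length(v), cd4_mean = mean(v), cd4_sd = stats::sd(v),
        cd4_median = stats::median(v),
        cd4_q1 = unname(stats::quantile(v, 0.25)),
        cd4_q3 = unname(stats::quantile(v, 0.75)),
        vl_n = length(d),
        vl_pct_above = if (length(d)) round_half_up(100 * mean(d), 1)
                       else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  }
  out <- rbind(one(series_cohort, "cohort"), one(series_surv, "surveillance"))
  rownames(out) <- NULL
  out
}

# correlation + Bland-Altman row for one site's paired quantitative measure
.corr_ba_row <- function(x, y, site, measure) {
  keep <- is.finite(x) & is.finite(y)
  n <- sum(keep)
  row <- data.frame(site = site, measure = measure, n_pairs = n,
                    r = NA_real_, r_p_value = NA_real_, r_band = NA_character_,
                    mean_diff = NA_real_, sd_diff = NA_real_,
                    ci_mean_low = NA_real_, ci_mean_high = NA_real_,
                    loa_low = NA_real_, loa_high = NA_real_,
                    ba_p_value = NA_real_, stringsAsFactors = FALSE)
  if (n >= 3 && stats::var(x[keep]) > 0 && stats::var(y[keep]) > 0) {
    pr <- pearson_r(x[keep], y[keep])
    row$r <- pr$r; row$r_p_value <- pr$p_value; row$r_band <- pr$band
  }
  if (n >= 2) {
    ba <- bland_altman(x[keep], y[keep])
    row$mean_diff <- ba$mean_diff; row$sd_diff <- ba$sd_diff
    row$ci_mean_low <- ba$ci_mean_low; row$ci_mean_high <- ba$ci_mean_high
    row$loa_low <- ba$loa_low; row$loa_high <- ba$loa_high
    row$ba_p_value <- ba$p_value
  }
  row
}

# kappa row for one site's paired categorical measure
.kappa_row <- function(a, b, site, measure, categories) {
  keep <- !is.na(a) & !is.na(b)
  if (!sum(keep)) {
    return(data.frame(site = site, measure = measure, n_pairs = 0L,
                      kappa = NA_real_, p_value = NA_real_,
                      band = NA_character_, degenerate = NA,
                      stringsAsFactors = FALSE))
  }
  k <- cohen_kappa(a[keep], b[keep], categories)
  data.frame(site = site, measure = measure, n_pairs = k$n_pairs,
             kappa = k$kappa, p_value = k$p_value, band = k$band,
             degenerate = k$degenerate, stringsAsFactors = FALSE)
}

#' Run the full validation pipeline
#'
#' Simulates (or reads) the paired registries, links them on the normalized
#' identity triple, censors both sources, applies the eligibility rules,
#' audits closest-date test matching, derives per-patient summary biomarkers
#' per source and computes the agreement battery, all stratified by site with
#' a "Total" row. Re-running with the same configuration (including seed)
#' reproduces every output exactly.
#'
#' @param config a [pipeline_config()].
#' @return object of class `validation_report`: list with `eligibility`
#'   (report row), `link` (`link_result`), `measures` (per-source per-patient
#'   derived measures), `first_series` (per-source long series),
#'   `match_audit` (paired-test data frame with `delta_days`),
#'   `n_dedup_dropped`, and the tables `rates`, `proportions`,
#'   `first_ten`, `correlation_agreement`, `kappa`. When
#'   `config$out_dir` is set each table is also written as CSV.
#' @export
run_pipeline <- function(config) {
  .check(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  log_stage <- function(...) message(sprintf(...))

  # -- data -----------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- generate_paired_registries(config$sim)
    cohort <- sim$cohort; surveillance <- sim$surveillance
    truth <- sim$truth
  } else {
    cohort <- read_registry(config$cohort_paths$patients,
                            config$cohort_paths$results)
    surveillance <- read_registry(config$surveillance_paths$patients,
                                  config$surveillance_paths$results)
    truth <- NULL
  }
  log_stage("data: %d cohort patients (%d results), %d surveillance patients (%d results)",
            nrow(cohort$patients), nrow(cohort$results),
            nrow(surveillance$patients), nrow(surveillance$results))

  # -- linkage --------------------------------------------------------------
  link <- link_identities(cohort$patients, surveillance$patients)
  log_stage("linkage: %d auto-matched, %d review-queue pairs",
            nrow(link$matched), nrow(link$review_queue))

  # surveillance results re-coded to cohort codes for linked patients
  surv_res <- surveillance$results
  hit <- match(surv_res$code, link$matched$surveillance_code)
  surv_res <- surv_res[!is.na(hit), , drop = FALSE]
  surv_res$code <- link$matched$cohort_code[hit[!is.na(hit)]]

  # -- censoring ------------------------------------------------------------
  admin <- config$admin_censor_date
  cohort_res <- censor_results(cohort$results, admin)
  surv_res <- censor_surveillance(surv_res, cohort_res, admin)
  log_stage("censoring: %d cohort / %d surveillance results admissible",
            nrow(cohort_res), nrow(surv_res))

  # -- eligibility ----------------------------------------------------------
  elig <- apply_eligibility(cohort$patients, link, cohort_res, admin,
                            convention = config$convention,
                            pre_cart_inclusive = config$pre_cart_inclusive)
  log_stage("eligibility: %d of %d eligible (no link %d, no labs %d, no post-cART labs %d)",
            elig$report$n_eligible, elig$report$n_enrolled,
            elig$report$excluded_no_link,
            elig$report$excluded_no_labs_followup,
            elig$report$excluded_no_labs_post_cart)

  # -- matching audit -------------------------------------------------------
  audit <- list(); n_dedup <- 0
  ckey <- paste(cohort_res$code, cohort_res$analyte, sep = "\r")
  skey <- paste(surv_res$code, surv_res$analyte, sep = "\r")
  csplit <- split(cohort_res, ckey)
  ssplit <- split(surv_res, skey)
  for (k in intersect(names(csplit), names(ssplit))) {
    code <- csplit[[k]]$code[1]
    if (!(code %in% elig$eligible)) next
    m <- match_results(csplit[[k]], ssplit[[k]], config$window_days)
    n_dedup <- n_dedup + m$n_dedup_dropped
    if (nrow(m$pairs)) {
      m$pairs$code <- code
      audit[[length(audit) + 1]] <- m$pairs
    }
  }
  match_audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(analyte = character(), date_a = as.Date(character()),
               date_b = as.Date(character()), delta_days = integer(),
               value_a = numeric(), value_b = numeric(),
               lod_a = numeric(), lod_b = numeric(), code = character())
  rownames(match_audit) <- NULL
  if (n_dedup > 0)
    log_stage("matching: dropped %d same-day duplicate tests", n_dedup)
  log_stage("matching: %d cross-source pairs within %d days",
            nrow(match_audit), config$window_days)

  # -- derivation -----------------------------------------------------------
  drv_c <- derive_measures(cohort$patients, cohort_res, elig$eligible, admin,
                           config$pre_cart_inclusive)
  drv_s <- derive_measures(cohort$patients, surv_res, elig$eligible, admin,
                           config$pre_cart_inclusive)
  mc <- drv_c$measures; ms <- drv_s$measures
  log_stage("derivation: %d eligible patients summarized per source", nrow(mc))

  sites <- sort(unique(mc$site))

  # -- tables ---------------------------------------------------------------
  rates <- .rates_table(mc, cohort_res, surv_res, sites)

  prop_cd4 <- .proportion_panel(mc$nadir_cd4_category, ms$nadir_cd4_category,
                                c("<200", "200-349", ">=350"),
                                config$B, .sub_seed(config$seed, 1))
  prop_cd4$measure <- "nadir_cd4"
  prop_vl <- .proportion_panel(mc$peak_vl_detectability,
                               ms$peak_vl_detectability,
                               c("below", "above"),
                               config$B, .sub_seed(config$seed, 2))
  prop_vl$measure <- "peak_vl"
  proportions <- rbind(prop_cd4, prop_vl)

  first_ten <- .first_series_table(drv_c$first_series, drv_s$first_series)

  ca <- list(); kp <- list()
  for (s in c(sites, "Total")) {
    idx <- if (s == "Total") rep(TRUE, nrow(mc)) else mc$site == s
    ca[[length(ca) + 1]] <- .corr_ba_row(mc$nadir_cd4[idx], ms$nadir_cd4[idx],
                                         s, "nadir_cd4")
    ca[[length(ca) + 1]] <- .corr_ba_row(mc$peak_vl_log10[idx],
                                         ms$peak_vl_log10[idx],
                                         s, "peak_vl_log10")
    kp[[length(kp) + 1]] <- .kappa_row(mc$nadir_cd4_category[idx],
                                       ms$nadir_cd4_category[idx],
                                       s, "nadir_cd4_category",
                                       c("<200", "200-349", ">=350"))
    kp[[length(kp) + 1]] <- .kappa_row(mc$peak_vl_detectability[idx],
                                       ms$peak_vl_detectability[idx],
                                       s, "peak_vl_detectability",
                                       c("below", "above"))
  }
  correlation_agreement <- do.call(rbind, ca)
  kappa_tab <- do.call(rbind, kp)
  rownames(correlation_agreement) <- rownames(kappa_tab) <- NULL

  report <- structure(
    list(eligibility = elig$report, link = link,
         measures = list(cohort = mc, surveillance = ms),
         first_series = list(cohort = drv_c$first_series,
                             surveillance = drv_s$first_series),
         match_audit = match_audit, n_dedup_dropped = n_dedup,
         rates = rates, proportions = proportions, first_ten = first_ten,
         correlation_agreement = correlation_agreement, kappa = kappa_tab,
         truth = truth, config = config),
    class = "validation_report"
  )

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(elig$report, file.path(d, "eligibility.csv"), row.names = FALSE)
    write_link_result(link, file.path(d, "linkage"))
    utils::write.csv(match_audit, file.path(d, "match_audit.csv"), row.names = FALSE)
    utils::write.csv(mc, file.path(d, "derived_cohort.csv"), row.names = FALSE)
    utils::write.csv(ms, file.path(d, "derived_surveillance.csv"), row.names = FALSE)
    utils::write.csv(rates, file.path(d, "rates.csv"), row.names = FALSE)
    utils::write.csv(proportions, file.path(d, "proportions.csv"), row.names = FALSE)
    utils::write.csv(first_ten, file.path(d, "first_ten.csv"), row.names = FALSE)
    utils::write.csv(correlation_agreement,
                     file.path(d, "correlation_agreement.csv"), row.names = FALSE)
    utils::write.csv(kappa_tab, file.path(d, "kappa.csv"), row.names = FALSE)
    log_stage("wrote tables under %s", d)
  }
  report
}

#' @export
print.validation_report <- function(x, ...) {
  e <- x$eligibility
  cat(sprintf("validation_report: %d/%d eligible patients, %d sites\n",
              e$n_eligible, e$n_enrolled,
              length(unique(x$measures$cohort$site))))
  tot_k <- x$kappa[x$kappa$site == "Total", ]
  tot_c <- x$correlation_agreement[x$correlation_agreement$site == "Total", ]
  for (i in seq_len(nrow(tot_c)))
    cat(sprintf("  r[%s] = %.3f (%s)\n", tot_c$measure[i], tot_c$r[i],
                tot_c$r_band[i]))
  for (i in seq_len(nrow(tot_k)))
    cat(sprintf("  kappa[%s] = %.3f (%s)\n", tot_k$measure[i],
                tot_k$kappa[i], tot_k$band[i]))
  invisible(x)
}
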