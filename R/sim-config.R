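#' Configuration for the paired-registry simulator
#'
#' Collects and validates every knob of the synthetic-data generator. The
#' defaults describe the study design being emulated: adults started on
#' combined antiretroviral therapy (cART) between 2003-01-01 and 2013-12-31
#' across 13 sites, administratively censored on 2014-07-31, monitored for
#' CD4+ T-cell counts and HIV viral load by two registries (a medical-record
#' cohort and a laboratory-surveillance system) that each observe the same
#' latent testing process imperfectly.
#'
#' @param n_patients number of patients to simulate.
#' @param n_sites number of cohort sites; patients are allocated uniformly.
#' @param enrollment_start,enrollment_end date interval within which cART
#'   start dates are drawn.
#' @param admin_censor_date administrative censoring date for the cohort.
#' @param testing_intensity expected tests per analyte per person-year in the
#'   latent process (each source then observes a thinned copy).
#' @param pre_cart_min_years,pre_cart_max_years pre-treatment in-care period:
#'   each patient's latent series starts uniformly between these many years
#'   before cART start.
#' @param dropout_mean_years mean of the exponential loss-to-follow-up time;
#'   follow-up ends at the earlier of dropout and administrative censoring.
#' @param missing_prob_cohort probability a latent test is absent from the
#'   cohort (medical-record) registry.
#' @param missing_prob_surveillance probability a latent test dated on/after
#'   `surveillance_full_coverage` is absent from the surveillance registry.
#' @param missing_prob_surveillance_early same, for tests dated before
#'   `surveillance_full_coverage`; early registry years were sparsely fed, so
#'   the default is substantially higher.
#' @param surveillance_full_coverage date from which the surveillance
#'   registry is considered fully operational.
#' @param typo_rate probability, per surveillance identity string (patient
#'   name and mother's name independently), of one injected character edit.
#' @param date_jitter_days maximum symmetric integer jitter (days) applied to
#'   the surveillance copy of a test date.
#' @param cd4_noise_sd SD (cells/mm3) of perturbation on the surveillance
#'   copy of a CD4 count.
#' @param vl_noise_sd SD (log10 copies/ml) of perturbation on the
#'   surveillance copy of a detectable viral load.
#' @param lod_schedule named numeric vector mapping calendar year to the
#'   viral-load lower limit of detection in copies/ml; limits stepped from
#'   400 down to 40 over the study era. Years outside the map use the
#'   nearest mapped year.
#' @param vl_suppressed_frac fraction of patients whose pre-treatment viral
#'   load is already below the detection limit (low-viremia controllers);
#'   keeps both levels of the detectability dichotomy populated.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       n_sites = 13,
                       enrollment_start = as.Date("2003-01-01"),
                       enrollment_end = as.Date("2013-12-31"),
                       admin_censor_date = as.Date("2014-07-31"),
                       testing_intensity = 2.9,
                       pre_cart_min_years = 0.25,
                       pre_cart_max_years = 2,
                       dropout_mean_years = 6,
                       missing_prob_cohort = 0.15,
                       missing_prob_surveillance = 0.08,
                       missing_prob_surveillance_early = 0.45,
                       surveillance_full_coverage = as.Date("2008-01-01"),
                       typo_rate = 0.0055,
                       date_jitter_days = 3,
                       cd4_noise_sd = 10,
                       vl_noise_sd = 0.08,
                       lod_schedule = c("2003" = 400, "2004" = 400,
                                        "2005" = 400, "2006" = 400,
                                        "2007" = 50, "2008" = 50,
                                        "2009" = 50, "2010" = 50,
                                        "2011" = 50, "2012" = 40,
                                        "2013" = 40, "2014" = 40),
                       vl_suppressed_frac = 0.03,
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients, n_sites = n_sites,
    enrollment_start = as.Date(enrollment_start),
    enrollment_end = as.Date(enrollment_end),
    admin_censor_date = as.Date(admin_censor_date),
    testing_intensity = testing_intensity,
    pre_cart_min_years = pre_cart_min_years,
    pre_cart_max_years = pre_cart_max_years,
    dropout_mean_years = dropout_mean_years,
    missing_prob_cohort = missing_prob_cohort,
    missing_prob_surveillance = missing_prob_surveillance,
    missing_prob_surveillance_early = missing_prob_surveillance_early,
    surveillance_full_coverage = as.Date(surveillance_full_coverage),
    typo_rate = typo_rate,
    date_jitter_days = date_jitter_days,
    cd4_noise_sd = cd4_noise_sd,
    vl_noise_sd = vl_noise_sd,
    lod_schedule = lod_schedule,
    vl_suppressed_frac = vl_suppressed_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' @param cfg a `sim_config` list.
#' @return `cfg` invisibly; errors name the offending field.
#' @export
validate_sim_config <- function(cfg) {
  .check(is.numeric(cfg$n_patients) && cfg$n_patients >= 1,
         "sim_config: n_patients must be a positive integer")
  .check(is.numeric(cfg$n_sites) && cfg$n_sites >= 1,
         "sim_config: n_sites must be a positive integer")
  .check(cfg$enrollment_start <= cfg$enrollment_end,
         "sim_config: enrollment_start must not be after enrollment_end")
  .check(cfg$enrollment_end < cfg$admin_censor_date,
         "sim_config: enrollment window must end before admin_censor_date")
  .check(cfg$testing_intensity > 0,
         "sim_config: testing_intensity must be > 0")
  .check(cfg$pre_cart_min_years > 0 &&
           cfg$pre_cart_max_years >= cfg$pre_cart_min_years,
         "sim_config: pre-cART period bounds invalid")
  .check(cfg$dropout_mean_years > 0,
         "sim_config: dropout_mean_years must be > 0")
  for (f in c("missing_prob_cohort", "missing_prob_surveillance",
              "missing_prob_surveillance_early", "typo_rate",
              "vl_suppressed_frac")) {
    .check(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
           "sim_config: ", f, " must lie in [0, 1]")
  }
  .check(cfg$date_jitter_days >= 0,
         "sim_config: date_jitter_days must be >= 0")
  .check(cfg$cd4_noise_sd >= 0, "sim_config: cd4_noise_sd must be >= 0")
  .check(cfg$vl_noise_sd >= 0, "sim_config: vl_noise_sd must be >= 0")
  .check(length(cfg$lod_schedule) >= 1 &&
           !is.null(names(cfg$lod_schedule)) &&
           all(cfg$lod_schedule >= 40 & cfg$lod_schedule <= 400),
         "sim_config: lod_schedule values must lie in [40, 400] copies/ml")
  .check(is.numeric(cfg$seed) && length(cfg$seed) == 1,
         "sim_config: seed must be a single integer")
  invisible(cfg)
}

#' Detection limit in force for a given collection date
#'
#' @param dates `Date` vector.
#' @param lod_schedule named vector, year -> copies/ml.
#' @return numeric vector of detection limits; dates outside the mapped years
#'   use the nearest mapped year.
#' @export
lod_for_date <- function(dates, lod_schedule) {
  yrs <- as.integer(format(as.Date(dates), "%Y"))
  sched_years <- as.integer(names(lod_schedule))
  idx <- vapply(yrs, function(y) which.min(abs(sched_years - y)), integer(1))
  unname(lod_schedule[idx])
}
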