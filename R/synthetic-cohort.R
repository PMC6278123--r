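# Paired-registry simulator: one latent laboratory-testing process per
# patient, observed imperfectly by two registries (medical-record cohort and
# laboratory surveillance). Ground truth (true links, latent series) is kept
# so downstream linkage/matching/agreement stages can be validated.

.first_names_f <- c("MARIA", "ANA", "FRANCISCA", "ANTONIA", "ADRIANA",
                    "JULIANA", "MARCIA", "FERNANDA", "PATRICIA", "ALINE",
                    "SANDRA", "CAMILA", "AMANDA", "BRUNA", "JESSICA",
                    "LETICIA", "SIMONE", "VANESSA", "ROSANGELA", "CLAUDIA")
.first_names_m <- c("JOSE", "JOAO", "ANTONIO", "FRANCISCO", "CARLOS",
                    "PAULO", "PEDRO", "LUCAS", "LUIZ", "MARCOS",
                    "GABRIEL", "RAFAEL", "DANIEL", "MARCELO", "BRUNO",
                    "EDUARDO", "FELIPE", "RODRIGO", "SERGIO", "RICARDO")
.surnames <- c("SILVA", "SANTOS", "OLIVEIRA", "SOUZA", "RODRIGUES", "LIMA",
               "ALVES", "FERREIRA", "PEREIRA", "GOMES", "COSTA", "RIBEIRO",
               "MARTINS", "CARVALHO", "ALMEIDA", "LOPES", "SOARES",
               "FERNANDES", "VIEIRA", "BARBOSA", "ROCHA", "DIAS", "NASCIMENTO",
               "ANDRADE", "MOREIRA", "NUNES", "MARQUES", "MACHADO", "MENDES",
               "FREITAS", "CARDOSO", "RAMOS", "GONCALVES", "SANTANA", "TEIXEIRA")

.typo_alphabet <- c(LETTERS, " ")

#' Inject a single character edit into a string
#'
#' Applies exactly one random single-character substitution, deletion or
#' insertion; the result always differs from the input (substitutions draw a
#' character different from the one replaced). Used to emulate typing errors
#' in registry identity fields.
#'
#' @param s non-empty character scalar.
#' @return `s` with one character edit (Levenshtein distance exactly 1).
#' @export
inject_typo <- function(s) {
  .check(is.character(s) && length(s) == 1 && nchar(s) >= 1,
         "inject_typo: s must be a non-empty string")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  # a 1-character string cannot be deleted (empty result would not be a
  # valid identity), so restrict to substitution/insertion there
  ops <- if (n == 1) c("sub", "ins") else c("sub", "del", "ins")
  op <- sample(ops, 1)
  if (op == "sub") {
    i <- sample.int(n, 1)
    repl <- sample(setdiff(.typo_alphabet, chars[i]), 1)
    chars[i] <- repl
    paste(chars, collapse = "")
  } else if (op == "del") {
    i <- sample.int(n, 1)
    paste(chars[-i], collapse = "")
  } else {
    i <- sample.int(n + 1, 1) # insert before position i
    ch <- sample(.typo_alphabet, 1)
    paste(c(chars[seq_len(i - 1)], ch, chars[seq(i, length.out = n - i + 1)]),
          collapse = "")
  }
}

# detectable-VL probability k years after cART start; declines as treatment
# suppresses viremia (values chosen to mimic a cohort where ~30% of first
# on-treatment loads are detectable, falling towards ~12%)
.p_detectable_post <- function(t_years) 0.12 + 0.25 * exp(-0.8 * t_years)

# one patient's latent series + registry copies; called under a per-patient
# RNG sub-stream so output is reproducible when n_patients changes
.simulate_patient <- function(i, cfg) {
  set.seed(.sub_seed(cfg$seed, i))
  site <- sprintf("S%02d", sample.int(cfg$n_sites, 1))
  span <- as.numeric(cfg$enrollment_end - cfg$enrollment_start)
  cart_start <- cfg$enrollment_start + floor(stats::runif(1) * (span + 1))
  age_years <- stats::runif(1, 18, 65)
  birth_date <- cart_start - round(age_years * 365.25)
  sex_f <- stats::runif(1) < 0.35
  first <- sample(if (sex_f) .first_names_f else .first_names_m, 1)
  sn <- sample(.surnames, 2)
  full_name <- paste(first, sn[1], sn[2])
  mother_name <- paste(sample(.first_names_f, 1), sample(.surnames, 1), sn[2])

  pre_years <- stats::runif(1, cfg$pre_cart_min_years, cfg$pre_cart_max_years)
  series_start <- cart_start - round(pre_years * 365.25)
  dropout <- cart_start + round(stats::rexp(1, 1 / cfg$dropout_mean_years) * 365.25)
  followup_end <- min(cfg$admin_censor_date, dropout)

  span_days <- as.numeric(followup_end - series_start)
  duration <- span_days / 365.25

  cd4_baseline <- stats::rlnorm(1, log(250), 0.6)
  vl_setpoint <- stats::rnorm(1, 4.5, 0.7)
  vl_suppressed_patient <- stats::runif(1) < cfg$vl_suppressed_frac

  out <- list()
  for (analyte in c("CD4", "VL")) {
    n_tests <- stats::rpois(1, cfg$testing_intensity * max(0, duration))
    if (n_tests == 0 || span_days <= 0) {
      out[[analyte]] <- NULL
      next
    }
    dates <- sort(series_start + floor(stats::runif(n_tests) * (span_days + 1)))
    t_years <- years_between(cart_start, dates) # negative before cART
    lod <- lod_for_date(dates, cfg$lod_schedule)

    if (analyte == "CD4") {
      recovery <- 1 + 0.18 * pmax(0, pmin(t_years, 4))
      value <- pmax(1, round(cd4_baseline * recovery *
                               exp(stats::rnorm(n_tests, 0, 0.25))))
      detectable <- rep(NA, n_tests)
      lod <- rep(NA_real_, n_tests)
    } else {
      log10v <- numeric(n_tests)
      pre <- t_years < 0
      log10v[pre] <- if (vl_suppressed_patient) {
        stats::rnorm(sum(pre), 1.0, 0.3)
      } else {
        stats::rnorm(sum(pre), vl_setpoint, 0.3)
      }
      if (any(!pre)) {
        det_draw <- stats::runif(sum(!pre)) < .p_detectable_post(t_years[!pre])
        lp <- ifelse(det_draw, stats::rnorm(sum(!pre), 3.0, 0.7),
                     stats::rnorm(sum(!pre), 1.0, 0.3))
        log10v[!pre] <- lp
      }
      copies <- 10^log10v
      detectable <- copies > lod
      # below-limit results are recorded at the limit itself
      value <- ifelse(detectable, round(copies), lod)
    }

    in_cohort <- stats::runif(n_tests) >= cfg$missing_prob_cohort
    p_surv <- ifelse(dates < cfg$surveillance_full_coverage,
                     cfg$missing_prob_surveillance_early,
                     cfg$missing_prob_surveillance)
    in_surv <- stats::runif(n_tests) >= p_surv

    if (cfg$date_jitter_days > 0) {
      jit <- sample(seq(-cfg$date_jitter_days, cfg$date_jitter_days),
                    n_tests, replace = TRUE)
    } else {
      jit <- rep(0L, n_tests)
    }
    surv_date <- dates + jit
    surv_lod <- if (analyte == "VL") lod_for_date(surv_date, cfg$lod_schedule)
                else rep(NA_real_, n_tests)

    if (analyte == "CD4") {
      surv_value <- pmax(1, round(value + stats::rnorm(n_tests, 0, cfg$cd4_noise_sd)))
      surv_detectable <- rep(NA, n_tests)
    } else {
      surv_value <- numeric(n_tests)
      surv_detectable <- logical(n_tests)
      det <- which(detectable)
      if (length(det)) {
        lg <- log10(value[det]) + stats::rnorm(length(det), 0, cfg$vl_noise_sd)
        cp <- round(10^lg)
        sd_flag <- cp > surv_lod[det]
        surv_value[det] <- ifelse(sd_flag, cp, surv_lod[det])
        surv_detectable[det] <- sd_flag
      }
      nd <- which(!detectable)
      if (length(nd)) {
        surv_value[nd] <- surv_lod[nd]
        surv_detectable[nd] <- FALSE
      }
    }

    out[[analyte]] <- list(
      analyte = rep(analyte, n_tests), date = dates, value = value,
      lod = lod, detectable = detectable,
      in_cohort = in_cohort, in_surveillance = in_surv,
      surv_date = surv_date, surv_value = surv_value, surv_lod = surv_lod,
      surv_detectable = surv_detectable
    )
  }

  surv_full_name <- full_name
  surv_mother_name <- mother_name
  if (cfg$typo_rate > 0) {
    if (stats::runif(1) < cfg$typo_rate) surv_full_name <- inject_typo(full_name)
    if (stats::runif(1) < cfg$typo_rate) surv_mother_name <- inject_typo(mother_name)
  }

  list(
    patient = list(
      site = site, full_name = full_name, mother_name = mother_name,
      birth_date = birth_date, cart_start = cart_start,
      followup_end = followup_end, series_start = series_start,
      surv_full_name = surv_full_name, surv_mother_name = surv_mother_name
    ),
    tests = out
  )
}

#' Generate a pair of synthetic registries with ground truth
#'
#' Simulates `n_patients` latent laboratory histories (CD4+ T-cell counts and
#' HIV viral loads around a cART start date) and the imperfect copies held by
#' two registries: a clinical cohort (subject to record-abstraction
#' missingness) and a laboratory-surveillance system (subject to its own
#' missingness — higher before its full-coverage date — plus date jitter,
#' value noise and identity typos). The latent biomarker model is a stand-in
#' chosen for qualitative realism, not a claim about any real population; see
#' the package vignette.
#'
#' @param config a [sim_config()] object.
#' @return object of class `paired_registries`: list with
#'   \describe{
#'     \item{cohort}{`patients` and `results` data frames (codes `C…`).}
#'     \item{surveillance}{`patients` and `results` data frames (codes `S…`);
#'       identity strings may carry typos, dates jitter, values noise.}
#'     \item{truth}{`code_map` (true cohort-to-surveillance links) and
#'       `latent` (one row per latent test with both registries' copies and
#'       inclusion flags).}
#'     \item{config}{the configuration used.}
#'   }
#'   Result tables have columns `code`, `analyte`, `collection_date`,
#'   `value`, `lod`; below-limit viral loads are recorded at the limit
#'   (`value == lod`), detectable ones strictly above it.
#' @export
generate_paired_registries <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  sims <- lapply(seq_len(n), .simulate_patient, cfg = config)

  ccode <- sprintf("C%05d", seq_len(n))
  scode <- sprintf("S%05d", seq_len(n))

  pats <- lapply(sims, `[[`, "patient")
  pull <- function(field) unlist(lapply(pats, `[[`, field), use.names = FALSE)
  pull_date <- function(field) as.Date(vapply(pats, function(p)
    as.character(p[[field]]), character(1)))

  cohort_patients <- data.frame(
    code = ccode,
    full_name = pull("full_name"),
    mother_name = pull("mother_name"),
    birth_date = pull_date("birth_date"),
    site = pull("site"),
    cart_start = pull_date("cart_start"),
    followup_end = pull_date("followup_end"),
    stringsAsFactors = FALSE
  )
  surveillance_patients <- data.frame(
    code = scode,
    full_name = pull("surv_full_name"),
    mother_name = pull("surv_mother_name"),
    birth_date = pull_date("birth_date"),
    site = pull("site"),
    cart_start = pull_date("cart_start"),
    followup_end = pull_date("followup_end"),
    stringsAsFactors = FALSE
  )

  blocks <- list()
  for (i in seq_len(n)) {
    for (analyte in names(sims[[i]]$tests)) {
      b <- sims[[i]]$tests[[analyte]]
      b$cohort_code <- rep(ccode[i], length(b$date))
      b$surveillance_code <- rep(scode[i], length(b$date))
      blocks[[length(blocks) + 1]] <- b
    }
  }
  cat_field <- function(field) unlist(lapply(blocks, `[[`, field), use.names = FALSE)
  latent <- data.frame(
    cohort_code = cat_field("cohort_code"),
    surveillance_code = cat_field("surveillance_code"),
    analyte = cat_field("analyte"),
    date = as.Date(cat_field("date"), origin = "1970-01-01"),
    value = cat_field("value"),
    lod = cat_field("lod"),
    detectable = cat_field("detectable"),
    in_cohort = cat_field("in_cohort"),
    in_surveillance = cat_field("in_surveillance"),
    surv_date = as.Date(cat_field("surv_date"), origin = "1970-01-01"),
    surv_value = cat_field("surv_value"),
    surv_lod = cat_field("surv_lod"),
    stringsAsFactors = FALSE
  )

  cohort_results <- data.frame(
    code = latent$cohort_code[latent$in_cohort],
    analyte = latent$analyte[latent$in_cohort],
    collection_date = latent$date[latent$in_cohort],
    value = latent$value[latent$in_cohort],
    lod = latent$lod[latent$in_cohort],
    stringsAsFactors = FALSE
  )
  surveillance_results <- data.frame(
    code = latent$surveillance_code[latent$in_surveillance],
    analyte = latent$analyte[latent$in_surveillance],
    collection_date = latent$surv_date[latent$in_surveillance],
    value = latent$surv_value[latent$in_surveillance],
    lod = latent$surv_lod[latent$in_surveillance],
    stringsAsFactors = FALSE
  )

  structure(
    list(
      cohort = list(patients = cohort_patients, results = cohort_results),
      surveillance = list(patients = surveillance_patients,
                          results = surveillance_results),
      truth = list(
        code_map = data.frame(cohort_code = ccode, surveillance_code = scode,
                              stringsAsFactors = FALSE),
        latent = latent,
        exposure = data.frame(
          cohort_code = ccode,
          series_start = pull_date("series_start"),
          followup_end = pull_date("followup_end"),
          stringsAsFactors = FALSE
        )
      ),
      config = config
    ),
    class = "paired_registries"
  )
}

#' @export
print.paired_registries <- function(x, ...) {
  cat(sprintf(
    "paired_registries: %d patients, %d sites\n  cohort: %d results; surveillance: %d results; latent tests: %d\n",
    nrow(x$cohort$patients), x$config$n_sites,
    nrow(x$cohort$results), nrow(x$surveillance$results),
    nrow(x$truth$latent)))
  invisible(x)
}

#' Write a registry pair to delimited text
#'
#' Writes `patients.csv` and `results.csv` for each registry (comma-separated
#' with a header row, ISO-8601 dates) under `dir/cohort` and
#' `dir/surveillance`, plus `truth_code_map.csv`.
#'
#' @param sim a `paired_registries` object.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_registries <- function(sim, dir) {
  for (src in c("cohort", "surveillance")) {
    d <- file.path(dir, src)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sim[[src]]$patients, file.path(d, "patients.csv"),
                     row.names = FALSE)
    utils::write.csv(sim[[src]]$results, file.path(d, "results.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(sim$truth$code_map, file.path(dir, "truth_code_map.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read one registry from delimited text
#'
#' @param patients_csv,results_csv paths to the two tables written by
#'   [write_registries()] (or equivalently laid-out real extracts).
#' @return list with `patients` and `results` data frames, dates parsed.
#' @export
read_registry <- function(patients_csv, results_csv) {
  patients <- utils::read.csv(patients_csv, stringsAsFactors = FALSE)
  for (f in c("birth_date", "cart_start", "followup_end")) {
    if (f %in% names(patients)) patients[[f]] <- as.Date(patients[[f]])
  }
  results <- utils::read.csv(results_csv, stringsAsFactors = FALSE)
  results$collection_date <- as.Date(results$collection_date)
  list(patients = patients, results = results)
}
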