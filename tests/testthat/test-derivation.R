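D <- function(...) as.Date(c(...))

res_df <- function(code, analyte, dates, values, lod = NA_real_) {
  data.frame(code = code, analyte = analyte, collection_date = as.Date(dates),
             value = values, lod = lod, stringsAsFactors = FALSE)
}

test_that("administrative censoring strictly removes later tests", {
  r <- res_df("C1", "CD4", D("2014-07-30", "2014-07-31", "2014-08-01"),
              c(1, 2, 3))
  kept <- censor_results(r, "2014-07-31")
  expect_equal(kept$value, c(1, 2))
  # unchanged when already within bounds; idempotent
  expect_equal(censor_results(kept, "2014-07-31"), kept)
})

test_that("censoring matches a direct filter oracle on random series", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    r <- res_df("C1", "CD4", D("2010-01-01") + sample(0:2000, n), rnorm(n))
    bound <- D("2010-01-01") + sample(0:2000, 1)
    got <- censor_results(r, bound)
    oracle <- r[r$collection_date <= bound, , drop = FALSE]
    expect_equal(got, oracle)
  }
})

test_that("surveillance is bounded by the cohort's last same-analyte date", {
  cohort <- res_df("C1", "CD4", D("2010-01-01", "2011-06-01"), c(1, 2))
  surv <- res_df("C1", "CD4", D("2011-05-30", "2011-06-01", "2011-06-02"),
                 c(9, 9, 9))
  kept <- censor_surveillance(surv, cohort, "2014-07-31")
  expect_equal(nrow(kept), 2) # the test after 2011-06-01 is removed
  # a different analyte is not bounded by the CD4 horizon
  surv_vl <- res_df("C1", "VL", D("2012-01-01"), 500, lod = 50)
  expect_equal(nrow(censor_surveillance(surv_vl, cohort, "2014-07-31")), 1)
  # but the administrative date still applies
  late <- res_df("C1", "VL", D("2014-08-02"), 500, lod = 50)
  expect_equal(nrow(censor_surveillance(late, cohort, "2014-07-31")), 0)
})

test_that("person_years divides day intervals by 365.25", {
  expect_equal(person_years(D("2003-01-01"), D("2004-01-01")),
               1, tolerance = 1 / 365.25)
  expect_equal(person_years(D("2003-01-01"), D("2003-01-01")), 0)
  expect_error(person_years(D("2003-01-02"), D("2003-01-01")), "precedes")
  # whole-cohort sum equals the per-patient oracle sum
  set.seed(3)
  start <- D("2003-01-01") + sample(0:3000, 50)
  bound <- start + sample(0:2000, 50)
  expect_equal(sum(person_years(start, bound)),
               sum(as.numeric(bound - start) / 365.25))
})

test_that("CD4 categories use the half-open middle bin", {
  expect_equal(categorize_cd4(c(0, 199, 200, 349, 349.9, 350, 1200)),
               c("<200", "<200", "200-349", "200-349", "200-349",
                 ">=350", ">=350"))
  expect_error(categorize_cd4(-1), "negative")
  # boundary sweep against an interval-membership oracle
  v <- seq(0, 500, by = 0.5)
  oracle <- ifelse(v < 200, "<200", ifelse(v < 350, "200-349", ">=350"))
  expect_equal(categorize_cd4(v), oracle)
})

test_that("viral-load dichotomization is strictly above the assay limit", {
  expect_equal(dichotomize_vl(500, 400), "above")
  expect_equal(dichotomize_vl(400, 400), "below")
  expect_equal(dichotomize_vl(c(39, 41), c(40, 40)), c("below", "above"))
  expect_true(is.na(dichotomize_vl(NA, 40)))
})

test_that("nadir CD4 takes the strict pre-treatment minimum, NDA when empty", {
  dates <- D("2009-01-01", "2009-06-01", "2009-12-01")
  got <- nadir_cd4_pre_cart(c(310, 180, 420), dates, "2010-01-01")
  expect_equal(got$nadir, 180)
  expect_equal(got$category, "<200")
  # same-day test is on-treatment by default...
  same_day <- nadir_cd4_pre_cart(100, D("2010-01-01"), "2010-01-01")
  expect_true(is.na(same_day$nadir))
  # ...but pre-cART when the inclusive switch is on
  expect_equal(nadir_cd4_pre_cart(100, D("2010-01-01"), "2010-01-01",
                                  pre_cart_inclusive = TRUE)$nadir, 100)
  # no pre-treatment tests at all -> NDA
  expect_true(is.na(nadir_cd4_pre_cart(numeric(0), D(), "2010-01-01")$nadir))
})

test_that("nadir/peak equal direct scan oracles on random series", {
  set.seed(27)
  cart <- D("2008-06-15")
  for (rep in 1:20) {
    n <- sample(1:25, 1)
    dates <- D("2007-01-01") + sample(0:1000, n)
    cd4 <- sample(10:1200, n, replace = TRUE)
    got <- nadir_cd4_pre_cart(cd4, dates, cart)
    pre <- dates < cart
    expect_equal(got$nadir, if (any(pre)) min(cd4[pre]) else NA_real_)
    if (any(pre)) expect_true(all(got$nadir <= cd4[pre]))

    lod <- rep(50, n)
    detectable <- runif(n) < 0.8
    copies <- ifelse(detectable, sample(51:1e6, n, replace = TRUE), 50)
    pk <- peak_vl_pre_cart(copies, lod, dates, cart)
    det_pre <- pre & detectable
    if (any(det_pre)) {
      expect_equal(pk$peak_copies, max(copies[det_pre]))
      expect_equal(pk$peak_log10, log10(max(copies[det_pre])))
      expect_equal(pk$detectability, "above")
      expect_true(all(pk$peak_log10 >= log10(copies[det_pre])))
    } else if (any(pre)) {
      expect_true(is.na(pk$peak_copies))
      expect_equal(pk$detectability, "below")
    } else {
      expect_true(is.na(pk$detectability))
    }
  }
})

test_that("all-below-limit pre-treatment loads yield qualitative-only peaks", {
  pk <- peak_vl_pre_cart(c(50, 50), c(50, 50),
                         D("2009-01-01", "2009-05-01"), "2010-01-01")
  expect_true(is.na(pk$peak_copies))
  expect_true(is.na(pk$peak_log10))
  expect_equal(pk$detectability, "below")
})

test_that("first-n post-treatment series is date-ordered and truncated", {
  dates <- D("2010-03-01", "2010-01-01", "2009-12-01", "2010-02-01")
  f <- first_n_post_cart(c(10, 20, 30, 40), dates, "2010-01-01", n = 10)
  expect_equal(f$value, c(20, 40, 10)) # pre-cART 2009-12-01 excluded
  expect_equal(f$index, 1:3)
  expect_equal(f$date, sort(dates[dates >= D("2010-01-01")]))
  f2 <- first_n_post_cart(1:20, D("2010-01-01") + 1:20, "2010-01-01", n = 10)
  expect_equal(nrow(f2), 10)
  expect_equal(f2$value, 1:10)
  f0 <- first_n_post_cart(numeric(0), D(), "2010-01-01")
  expect_equal(nrow(f0), 0)
})

test_that("eligibility applies the three exclusion reasons in order", {
  pats <- data.frame(
    code = c("C1", "C2", "C3", "C4"),
    full_name = paste("P", 1:4), mother_name = paste("M", 1:4),
    birth_date = D(rep("1970-01-01", 4)),
    site = "S01",
    cart_start = D(rep("2010-01-01", 4)),
    followup_end = D(rep("2012-01-01", 4)),
    stringsAsFactors = FALSE
  )
  link <- structure(list(
    matched = data.frame(cohort_code = c("C1", "C2", "C3"),
                         surveillance_code = c("S1", "S2", "S3"),
                         stringsAsFactors = FALSE)),
    class = "link_result")
  results <- rbind(
    res_df("C1", "CD4", D("2010-02-01"), 300),       # eligible
    res_df("C2", "CD4", D("2009-06-01"), 250),       # labs only pre-cART
    res_df("C4", "CD4", D("2010-02-01"), 300)        # not linked
  )
  out <- apply_eligibility(pats, link, results, "2014-07-31")
  expect_equal(out$eligible, "C1")
  rep <- out$report
  expect_equal(rep$excluded_no_link, 1)             # C4: first reason wins
  expect_equal(rep$excluded_no_labs_followup, 1)    # C3: no labs at all
  expect_equal(rep$excluded_no_labs_post_cart, 1)   # C2
  expect_equal(rep$n_eligible + rep$excluded_no_link +
                 rep$excluded_no_labs_followup + rep$excluded_no_labs_post_cart,
               rep$n_enrolled)
})

test_that("eligibility counts equal a per-patient rule oracle on synthetic data", {
  s <- generate_paired_registries(tiny_sim(n = 150, seed = 44, typo_rate = 0.3))
  link <- link_identities(s$cohort$patients, s$surveillance$patients)
  admin <- s$config$admin_censor_date
  res <- censor_results(s$cohort$results, admin)
  out <- apply_eligibility(s$cohort$patients, link, res, admin)

  oracle <- vapply(seq_len(nrow(s$cohort$patients)), function(i) {
    code <- s$cohort$patients$code[i]
    if (!(code %in% link$matched$cohort_code)) return("no_link")
    mine <- res[res$code == code, , drop = FALSE]
    if (!nrow(mine)) return("no_labs_followup")
    if (!any(mine$collection_date >= s$cohort$patients$cart_start[i]))
      return("no_labs_post_cart")
    "eligible"
  }, character(1))
  expect_equal(out$report$excluded_no_link, sum(oracle == "no_link"))
  expect_equal(out$report$excluded_no_labs_followup,
               sum(oracle == "no_labs_followup"))
  expect_equal(out$report$excluded_no_labs_post_cart,
               sum(oracle == "no_labs_post_cart"))
  expect_setequal(out$eligible, s$cohort$patients$code[oracle == "eligible"])
})

test_that("derived measures respect their own invariants on synthetic data", {
  s <- generate_paired_registries(tiny_sim(n = 100, seed = 58))
  link <- link_identities(s$cohort$patients, s$surveillance$patients)
  admin <- s$config$admin_censor_date
  res <- censor_results(s$cohort$results, admin)
  elig <- apply_eligibility(s$cohort$patients, link, res, admin)
  drv <- derive_measures(s$cohort$patients, res, elig$eligible, admin)
  m <- drv$measures

  expect_setequal(m$code, elig$eligible)
  expect_true(all(m$person_years > 0))
  # category consistent with the quantitative nadir
  has <- !is.na(m$nadir_cd4)
  expect_equal(m$nadir_cd4_category[has], categorize_cd4(m$nadir_cd4[has]))
  expect_true(all(is.na(m$nadir_cd4_category[!has])))
  # detectability "above" implies a quantitative peak, log10 consistent
  ab <- !is.na(m$peak_vl_detectability) & m$peak_vl_detectability == "above"
  expect_true(all(!is.na(m$peak_vl_log10[ab])))
  expect_equal(m$peak_vl_log10[ab], log10(m$peak_vl_copies[ab]))
  # first-series length caps at 10 per analyte
  cnt <- tapply(drv$first_series$index,
                paste(drv$first_series$code, drv$first_series$analyte), max)
  expect_true(all(cnt <= 10))
  # category marginals (including NDA) sum to the eligible count
  tabs <- table(m$nadir_cd4_category, useNA = "always")
  expect_equal(sum(tabs), nrow(m))
})
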