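test_that("testing rates floor to integers per 100 person-years", {
  r <- testing_rate(80302, 32397)
  expect_identical(r$rate_per_100py, 247L)
  expect_identical(testing_rate(0, 100)$rate_per_100py, 0L)
  # flooring, not rounding: 99.9 tests per 100 py reports as 99
  expect_identical(testing_rate(999, 1000)$rate_per_100py, 99L)
  expect_error(testing_rate(10, 0), "person_years")
})

test_that("bootstrap proportion CI matches degenerate and Wald limits", {
  z <- proportion_ci(0, 100, seed = 1)
  expect_equal(z$p_hat, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))

  f <- proportion_ci(100, 100, seed = 1)
  expect_equal(c(f$p_hat, f$ci_low, f$ci_high), c(100, 100, 100))

  # large-n bootstrap percentile endpoints sit close to the Wald interval
  for (case in list(c(3878, 8007), c(2153, 8007), c(500, 1000))) {
    k <- case[1]; n <- case[2]
    ci <- proportion_ci(k, n, B = 1000, seed = 42)
    p <- k / n
    wald <- 100 * (p + c(-1, 1) * qnorm(0.975) * sqrt(p * (1 - p) / n))
    expect_lt(abs(ci$ci_raw[1] - wald[1]), 0.2)
    expect_lt(abs(ci$ci_raw[2] - wald[2]), 0.2)
    expect_lte(ci$ci_low, ci$p_hat)
    expect_gte(ci$ci_high, ci$p_hat)
  }
  expect_error(proportion_ci(5, 4, seed = 1), "exceed")
})

test_that("bootstrap CI width shrinks with sample size at fixed proportion", {
  w <- function(k, n) {
    ci <- proportion_ci(k, n, B = 1000, seed = 99)
    ci$ci_raw[2] - ci$ci_raw[1]
  }
  expect_lt(w(1200, 4000), w(300, 1000))
})

test_that("pearson_r equals the direct covariance formula and cor.test", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.6 * x + rnorm(n, sd = 0.8)
    got <- pearson_r(x, y)
    ora <- oracle_pearson(x, y)
    expect_equal(got$r, ora$r, tolerance = 1e-12)
    expect_equal(got$p_value, ora$p, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("pearson_r handles exact, inverted and degenerate inputs", {
  x <- c(1, 2, 4, 8, 9)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(2, 5)), "variance")
  expect_error(pearson_r(x[1:2], x[1:2]), "3 complete pairs")
  # pairwise-complete: NA pairs dropped
  y <- x; y[2] <- NA
  expect_equal(pearson_r(x, y)$n, 4)
})

test_that("pearson_r is invariant under affine transformation", {
  set.seed(8)
  x <- rnorm(25); y <- rnorm(25) + 0.5 * x
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3.2 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.01 * y - 2)$r, r0, tolerance = 1e-12)
})

test_that("bland_altman matches the formula oracle and t.test", {
  set.seed(12)
  for (rep in 1:15) {
    n <- sample(4:30, 1)
    x <- rnorm(n, 100, 15)
    y <- x + rnorm(n, 1, 5)
    got <- bland_altman(x, y)
    ora <- oracle_bland_altman(x, y)
    expect_equal(got$mean_diff, ora$mean, tolerance = 1e-10)
    expect_equal(got$sd_diff, ora$sd, tolerance = 1e-10)
    expect_equal(c(got$ci_mean_low, got$ci_mean_high), ora$ci, tolerance = 1e-10)
    expect_equal(c(got$loa_low, got$loa_high), ora$loa, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
    expect_equal(got$p_value, t.test(x - y)$p.value, tolerance = 1e-10)
    expect_lte(got$loa_low, got$mean_diff)
    expect_gte(got$loa_high, got$mean_diff)
    if (n > 4) {
      expect_lt(got$ci_mean_high - got$ci_mean_low,
                got$loa_high - got$loa_low)
    }
  }
})

test_that("bland_altman degenerate difference vectors follow the convention", {
  x <- c(3, 5, 9, 11)
  same <- bland_altman(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  off <- bland_altman(x, x - 2.5)
  expect_equal(off$mean_diff, 2.5)
  expect_equal(off$sd_diff, 0)
  expect_equal(c(off$loa_low, off$loa_high), c(2.5, 2.5))
  expect_true(is.na(off$p_value))
  expect_error(bland_altman(1, 2), "2 complete pairs")
})

test_that("cohen_kappa equals direct p_o/p_e arithmetic on a 2x2 table", {
  # counts [[20, 5], [10, 65]]
  a <- rep(c(1L, 1L, 2L, 2L), c(20, 5, 10, 65))
  b <- rep(c(1L, 2L, 1L, 2L), c(20, 5, 10, 65))
  got <- cohen_kappa(letters[a], letters[b])
  expect_equal(got$kappa, oracle_kappa(a, b), tolerance = 1e-12)
  # hand arithmetic: p_o = 0.85, p_e = 0.25*0.30 + 0.75*0.70 = 0.6
  expect_equal(got$kappa, (0.85 - 0.6) / (1 - 0.6), tolerance = 1e-12)
  expect_equal(got$p_o, 0.85)
  expect_equal(got$p_e, 0.6)
})

test_that("cohen_kappa equals the formula oracle on random tables", {
  set.seed(91)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    n <- sample(30:200, 1)
    pr <- draw_confused_pair(n, runif(1, 0.3, 0.95), rep(1 / k, k))
    got <- cohen_kappa(letters[pr$a], letters[pr$b], categories = letters[1:k])
    expect_equal(got$kappa, oracle_kappa(pr$a, pr$b, k), tolerance = 1e-12)
  }
})

test_that("cohen_kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(14)
  pr <- draw_confused_pair(400, 0.8, c(0.5, 0.3, 0.2))
  got <- cohen_kappa(letters[pr$a], letters[pr$b], categories = letters[1:3])
  tab <- table(factor(pr$a, 1:3), factor(pr$b, 1:3))
  expect_equal(got$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-10)
})

test_that("cohen_kappa is 1 on perfect agreement and ~0 under independence", {
  a <- rep(c("x", "y", "z"), c(30, 40, 30))
  perfect <- cohen_kappa(a, a)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$band, "almost perfect agreement")

  set.seed(5)
  n <- 4000
  ai <- sample(c("x", "y", "z"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  bi <- sample(c("x", "y", "z"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  ind <- cohen_kappa(ai, bi)
  # null SE of kappa is approximately 1/((1-p_e) sqrt(n)) scaled; use 3 SE
  se_null <- 1 / sqrt(n * (1 - ind$p_e))
  expect_lt(abs(ind$kappa), 3 * se_null)
})

test_that("cohen_kappa flags degenerate tables per the perfect-diagonal rule", {
  one <- cohen_kappa(rep("above", 10), rep("above", 10),
                     categories = c("below", "above"))
  expect_equal(one$kappa, 1)
  expect_true(one$degenerate)
  expect_true(is.na(one$p_value))

  two <- cohen_kappa(rep("x", 8), rep("y", 8))
  expect_true(two$degenerate)
  expect_true(is.na(two$kappa))
})

test_that("interpretation bands resolve the printed overlaps deterministically", {
  expect_equal(interpret_kappa(0.932), "almost perfect agreement")
  expect_equal(interpret_kappa(0), "less than chance agreement")
  expect_equal(interpret_kappa(0.80), "substantial agreement")
  expect_equal(interpret_kappa(0.81), "almost perfect agreement")
  expect_equal(interpret_kappa(-0.4), "less than chance agreement")
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")

  expect_equal(interpret_r(0.971), "very high correlation")
  expect_equal(interpret_r(0.90), "very high correlation")
  expect_equal(interpret_r(-0.95), "very high correlation")
  expect_equal(interpret_r(0.70), "high correlation")
  expect_equal(interpret_r(0.1), "negligible correlation")
  expect_error(interpret_r(-2), "\\[-1, 1\\]")
})

test_that("percentage helpers implement both printing conventions", {
  expect_equal(round_half_up(1.568, 1), 1.6)
  expect_equal(trunc_digits(1.568, 1), 1.5)
  expect_equal(pct_of(136, 8674), 1.6)
  expect_equal(pct_of(100, 8674, convention = "truncate"), 1.1)
  expect_equal(pct_of(431, 8674, convention = "truncate"), 4.9)
})
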