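# Independent oracles used across the suite. Each is a deliberately naive
# implementation (dynamic programming, exhaustive enumeration, direct formula
# arithmetic) kept free of the package's own code paths.

# Levenshtein edit distance, full DP table
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# exhaustive maximum-cardinality one-to-one matching within a day window;
# recursion over the first series' indices (feasible for <= 6 per side)
oracle_max_matching <- function(dates_a, dates_b, window = 30) {
  na <- length(dates_a); nb <- length(dates_b)
  admissible <- outer(seq_len(na), seq_len(nb), function(i, j)
    abs(as.integer(dates_b[j] - dates_a[i])) <= window)
  best <- function(i, used_b) {
    if (i > na) return(0L)
    res <- best(i + 1, used_b) # leave a[i] unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && admissible[i, j]) {
        ub <- used_b; ub[j] <- TRUE
        res <- max(res, 1L + best(i + 1, ub))
      }
    }
    res
  }
  best(1L, rep(FALSE, nb))
}

# direct-formula kappa from two category vectors (integer codes 1..k)
oracle_kappa <- function(a, b, k = max(a, b)) {
  n <- length(a)
  tab <- matrix(tabulate((a - 1L) * k + b, k * k), k, k, byrow = TRUE)
  po <- sum(diag(tab)) / n
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  pe <- sum(pr * pc)
  (po - pe) / (1 - pe)
}

# direct-formula Pearson r and its t-test p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# direct-formula Bland-Altman quantities
oracle_bland_altman <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  se <- s / sqrt(n)
  list(mean = m, sd = s,
       ci = m + c(-1, 1) * qt(0.975, n - 1) * se,
       loa = m + c(-1, 1) * 1.96 * s,
       p = 2 * pt(-abs(m / se), n - 1))
}

# draw a category pair sample under a confusion model: rater b agrees with
# rater a with probability conc, otherwise picks uniformly among the other
# categories
draw_confused_pair <- function(n, conc, probs) {
  k <- length(probs)
  a <- sample.int(k, n, replace = TRUE, prob = probs)
  agree <- runif(n) < conc
  b <- a
  flip <- which(!agree)
  if (length(flip)) {
    b[flip] <- vapply(a[flip], function(ai)
      sample(setdiff(seq_len(k), ai), 1L), integer(1))
  }
  list(a = a, b = b)
}

# analytic kappa implied by the confusion model above
analytic_confusion_kappa <- function(conc, probs) {
  k <- length(probs)
  q <- conc * probs + (1 - conc) * (1 - probs) / (k - 1)
  pe <- sum(probs * q)
  (conc - pe) / (1 - pe)
}

# small fast sim config for pipeline-level tests
tiny_sim <- function(n = 120, seed = 11, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# a fully clean configuration: the two registries observe the latent
# process identically (no missingness, typos, jitter or noise)
clean_sim <- function(n = 150, seed = 5, ...) {
  sim_config(n_patients = n, seed = seed,
             missing_prob_cohort = 0, missing_prob_surveillance = 0,
             missing_prob_surveillance_early = 0, typo_rate = 0,
             date_jitter_days = 0, cd4_noise_sd = 0, vl_noise_sd = 0, ...)
}
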