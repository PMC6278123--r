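---
title: "Validating cohort biomarkers against a surveillance registry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cohort biomarkers against a surveillance registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortagree)
```

# The validation design

`cohortagree` implements a biomarker-validation design for HIV cohorts: the
CD4+ T-cell counts and viral loads abstracted from medical records are
compared, patient by patient, against the same biomarkers held by a national
laboratory-surveillance registry. The comparison has five stages — record
linkage, censoring, eligibility, closest-date test matching, and per-patient
derivation — followed by an agreement battery. This vignette explains each
stage's model and assumptions, the tunable parameters, the numerical
conventions, and the design choices that were genuinely open.

## Record linkage

The only identity fields shared by the two registries are the patient's
name, the mother's name, and the birth date. Linkage is therefore
deterministic: names are normalized (upper case, Latin-ASCII
transliteration of diacritics, whitespace collapsed) and a pair is
auto-linked **iff all three normalized fields are equal** and the triple is
unambiguous on both sides. This mirrors validation practice in registries
where only 100%-compatible records receive a shared code and everything
else is reviewed by hand.

Two classes of pairs enter the review queue instead of being auto-linked:

* **ambiguous ties** — several records share one triple; auto-linking any of
  them would risk a false match, so none is linked;
* **two-of-three near misses** — pairs agreeing on exactly two normalized
  fields. A single typing error in one field produces exactly this
  signature. The two-of-three rule is our design choice: manual review of
  non-matches needs a candidate set, and requiring agreement on two fields
  keeps the queue small while catching one-field typos, including day/month
  swaps in the birth date (which we deliberately compare by exact calendar
  equality rather than fuzzily).

Unparseable birth dates become `NA`, which compares unequal to everything:
such records cannot auto-match and surface through the queue, never being
silently dropped. No probabilistic (Fellegi–Sunter) or phonetic matching is
attempted — the design under validation is exact matching plus manual
review, and the pipeline only *emits* the queue; adjudication is out of
scope.

## Censoring

The cohort is censored at an administrative date (default 2014-07-31, with
treatment starts enrolled 2003–2013). The surveillance series of each
patient is additionally truncated at the cohort's **last same-analyte test
date**, so the registry cannot contribute results beyond the cohort's own
recording horizon — otherwise the registry's longer reach would inflate its
test counts purely by construction. When the cohort recorded no test of an
analyte for a patient, we take the lenient reading and bound the
surveillance series by the administrative date alone. Censoring is a pure
date filter: it is idempotent and commutes with the eligibility rules.

## Eligibility

Patients are excluded in a fixed order, first reason wins: (1) no
surveillance link; (2) no cohort laboratory result during follow-up; (3) no
cohort result after starting combined antiretroviral therapy (cART).
Percentages in the eligibility report are printed to one decimal.
Registries in this field print such percentages inconsistently — some
figures truncate, some round — so both conventions are supported
(`convention = "half_up"`, the default, or `"truncate"`).

## Closest-date test matching

Cross-source comparisons of individual tests pair each result with the
same-analyte result of the other source at the **closest collection date,
within an inclusive 30-day window** (|Δ| ≤ 30; inclusivity at exactly 30
days is our call — the design rule names the interval, not its boundary),
one-to-one. Same-day duplicates within one source are first reduced to the
earliest-entered record.

The pairing rule is **greedy by smallest |Δ|**, ties broken by earlier
cohort date, then earlier surveillance date — fully deterministic. Greedy
selection is near-optimal but *not* guaranteed to pair the maximum possible
number of tests. The minimal counterexample, with window 30:
cohort tests on days {0, 10}, surveillance tests on days {9, 40}. Greedy
takes (10, 9) at |Δ| = 1, stranding day 0 (its only remaining partner, day
40, is out of window); pairing (0, 9) and (10, 40) would match both. On
random small instances the shortfall occurs in roughly one instance in ten
(the property test reports every counterexample it finds). We keep greedy
as the default nonetheless: it is simple, order-free and deterministic,
and an optimal assignment solver is deliberately out of scope — the
exhaustive matcher exists only as a test oracle. Matched deltas are emitted
in an audit table for quality control.

## Per-patient derivation

* **"Before cART" is strictly before the cART start date.** Labs drawn on
  the treatment-start day are conventionally baseline-on-treatment, so they
  count as post-cART by default; `pre_cart_inclusive = TRUE` flips this.
* **Nadir CD4** = minimum pre-cART count, categorized `<200`, `[200, 350)`,
  `≥350` cells/mm³ (half-open middle bin).
* **Peak viral load** = maximum pre-cART *detectable* load, reported as
  copies/ml and log₁₀(copies/ml) — log base 10 is the virology standard.
  Below-limit results participate qualitatively ("below") but are excluded
  from the quantitative maximum; a patient whose pre-cART loads are all
  below the limit gets detectability "below" with no quantitative peak; a
  patient with no pre-cART test at all is NDA ("no data available"). NDA
  propagates — there is no imputation.
* **Detectability** is "above" iff the result exceeded its own assay's
  lower limit of detection; the limit is era-specific (400 down to 40
  copies/ml over the study years). Below-limit results are *encoded* at the
  limit itself (`value == lod`), which keeps the result tables to five
  columns and makes `value > lod` the exact detectability test.
* **First-ten series** = the first ten post-cART results, ascending by
  date; shorter series are kept as-is.
* **Person-years** = days from cART start to the follow-up bound / 365.25.

## The agreement battery

* **Testing rates**: `⌊100·n/py⌋` per 100 person-years. Flooring, not
  rounding, is the deliberate convention: it is the only one consistent
  across the published totals this package's acceptance checks reproduce.
* **Proportions** carry 95% percentile-bootstrap confidence intervals with
  B = 1000 resamples. Resampling n binary observations with replacement is
  distributionally identical to drawing Binomial(n, p̂) counts, which is how
  the resamples are generated; the seed is mandatory. Point estimates are
  rounded half-up to one decimal. Proportion panels are reported twice:
  over all eligible patients (NDA as its own category) and "disconsidering
  NDA".
* **Pearson r** uses pairwise-complete pairs and the exact *t* transform
  for its p-value. Zero-variance input is an error naming the series.
* **Bland–Altman**: differences d = x − y; mean difference with *t*-based
  95% CI, limits of agreement d̄ ± 1.96·s_d, and a two-sided one-sample
  *t*-test of zero mean difference. Both the CI of the mean difference and
  the limits of agreement are reported side by side — published agreement
  tables often print a single ambiguous "CI" column, and we do not guess
  which one it is. Degenerate input (constant differences) reports p = 1
  when the differences are identically zero (the statistic is 0) and NA
  otherwise, mirroring the convention of not computing the test when the
  SD is zero.
* **Cohen's kappa** is unweighted — the standard interpretation cutoffs are
  defined for plain kappa, and the CD4 bins, though ordered, are few. The
  p-value is an asymptotic z-test against κ = 0 with the Fleiss null
  standard error; the construction of kappa p-values is not standardized in
  the literature this design follows, and the null z-test is our choice.
  Degenerate tables (fewer than two observed categories in each margin) are
  flagged: a perfectly diagonal single-category table still reports κ = 1 —
  agreement *is* perfect, only the chance correction is unidentifiable, so
  the p-value is NA.
* **Interpretation bands.** The printed cutoff lists in the agreement
  literature overlap at their interval ends (e.g. "moderate 0.50–0.80" vs
  "high 0.70–0.90" for correlations). Kappa bands are implemented
  upper-closed — (0.80, 1] is "almost perfect", 0 itself falls in "less
  than chance" — while correlation bands are lower-closed so that
  r = 0.90 is "very high". The slight asymmetry keeps each worked
  boundary case in its conventional band.

## The synthetic paired-registry generator

No public data exist for this design — the real registries hold
confidential clinical records — so the generator is a first-class module
with ground truth, not a fixture. Each patient has **one latent testing
process**: test times are Poisson with `testing_intensity` (default 2.9
tests per analyte per person-year) from a pre-treatment in-care start
(uniform 0.25–2 years before cART) to the end of follow-up
(exponential loss to follow-up, mean 6 years, truncated at the
administrative date). Each registry then observes a thinned, perturbed copy:

| parameter | default | role |
|---|---|---|
| `missing_prob_cohort` | 0.15 | test absent from the medical-record copy |
| `missing_prob_surveillance` | 0.08 | test absent from the registry, full-coverage era |
| `missing_prob_surveillance_early` | 0.45 | same, before `surveillance_full_coverage` (2008) |
| `typo_rate` | 0.0055 | one character edit per surveillance name string |
| `date_jitter_days` | 3 | symmetric jitter on surveillance test dates |
| `cd4_noise_sd` | 10 cells/mm³ | noise on the surveillance CD4 copy |
| `vl_noise_sd` | 0.08 log₁₀ | noise on detectable surveillance loads |
| `vl_suppressed_frac` | 0.03 | patients with below-limit pre-cART viremia |

The era-split surveillance missingness reproduces the structural feature
this design must cope with: laboratory registries were sparsely fed in
their first years, so pre-treatment summary measures are missing far more
often on the surveillance side even though the registry holds *more* tests
overall in later years. The default `typo_rate` makes the expected
exact-linkage failure fraction 1 − (1 − t)² ≈ 1.1%, the linkage-failure
share typical of this design's setting. Typos are injected only into the
surveillance identities — one dirty source suffices to exercise the review
queue — and only into the two name strings.

The latent biomarker values are **stand-ins chosen for qualitative realism,
not claims about any population**: CD4 is lognormal around a patient-level
baseline (median 250 cells/mm³) with a linear on-treatment recovery ramp
(+18%/year, capped at 4 years); pre-treatment log₁₀ viral load is normal
around a patient setpoint (mean 4.5, SD 0.7), and on-treatment loads are
detectable with probability 0.12 + 0.25·e^(−0.8t), mimicking progressive
suppression. Dates are ISO-8601 calendar dates; all intervals use
days/365.25. A single master seed drives everything, with per-patient
sub-streams so that enlarging the cohort leaves earlier patients'
trajectories unchanged.

**What passing tests therefore show — and what they do not.** The generator
reproduces the *statistical structure the validation assumes* (two noisy
views of one process, era-dependent registry coverage, identity typos); it
does not reproduce real-world features such as site-specific testing
cultures, assay batch effects, correlated missingness between analytes,
transcription errors in the values themselves, or patients who move between
sites. Agreement recovered on synthetic data validates the pipeline's
*arithmetic and logic*, not the quality of any real registry.

## Determinism and numerical conventions

Every stochastic step — simulation, bootstrap, analysis — descends from one
integer seed; reruns are byte-identical. Percentages print half-up to one
decimal (truncation available); rates floor to integers; all date
arithmetic is in days/365.25. Statistical functions are validated against
independent oracles (direct-formula arithmetic, dynamic-programming edit
distance, exhaustive matching enumeration) to 1e-10 or tighter, and kappa
additionally against an independent library implementation.

Problem sizes used by the test suite are deliberate choices: unit
properties run on tens of cases; pipeline properties on cohorts of
100–200 patients; the zero-discordance end-to-end control on 2,000
patients across 13 sites (which must recover κ = 1 and r = 1 exactly at
every site); and the kappa parameter-recovery study on 200 replicates of
400 pairs with 300 bootstrap resamples each, requiring the percentile
interval to cover the analytic kappa of the generating confusion model in
at least 90% of replicates.

## Known limitations

* Linkage is exact-only by design; heavy typo rates defeat it (that is the
  point of the review queue, whose adjudication is manual and out of
  scope).
* The greedy matcher can pair fewer tests than the optimum (example above);
  its audit table makes the realized pairing inspectable.
* The generator's biomarker distributions are stand-ins; per-site testing
  rates are not calibrated to any real cohort.
* NDA handling is exclusion-based throughout; no imputation, no weighting.
* Kappa is unweighted and its p-value asymptotic; exact or bootstrap kappa
  inference is not implemented (the bootstrap machinery exists only for
  proportions and in the test harness).
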