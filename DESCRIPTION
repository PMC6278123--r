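Package: cohortagree
Title: Validation of Clinical-Cohort Laboratory Biomarkers Against
    Surveillance Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating longitudinal laboratory biomarkers
    abstracted from clinical-cohort medical records against an independent
    laboratory-surveillance registry. Implements deterministic record
    linkage on normalized identity triples with a manual-review queue,
    closest-date one-to-one matching of laboratory results within a day
    window, derivation of per-patient pre-treatment summary biomarkers
    (nadir CD4+ T-cell count, peak viral load) under administrative and
    source-specific censoring rules, and an agreement battery: testing
    rates per 100 person-years, bootstrap percentile confidence intervals
    for proportions, Pearson correlation, Bland-Altman analysis, and
    Cohen's kappa with standard interpretation bands. A synthetic-data
    generator emulates two registries observing one latent test process
    per patient, with source-specific missingness, identity typos, date
    jitter and value noise, so the whole pipeline can be exercised and
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
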