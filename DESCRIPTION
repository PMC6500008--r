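Package: colonsurv
Title: Comparative Effectiveness of Post-Treatment Surveillance in Colon Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for claims-based comparative-effectiveness
    analysis of post-treatment surveillance testing in stage II/III colon
    cancer. Turns dated service claims (surgery, chemotherapy, CEA tests,
    CT/PET scans, colonoscopies) into per-year deduplicated surveillance
    counts anchored at the final treatment date, classifies patients as
    More Adherent, Less Adherent or Nonadherent against guideline minima,
    estimates propensity scores for surveillance intensity with gradient
    boosted classification trees using balance-driven iteration selection,
    forms average-treatment-effect inverse probability of treatment weights
    with standardized-mean-difference balance diagnostics, and fits
    IPTW-weighted Kaplan-Meier curves, log-rank tests and cause-specific
    Cox models with robust variance. Includes a seeded synthetic
    administrative-claims cohort generator with confounding by indication
    and competing cause-specific mortality for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
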