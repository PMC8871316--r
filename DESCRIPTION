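Package: nodulevol
Title: Measured Versus Diameter-Estimated Nodule Volume in Lung Cancer
    Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares semi-automated measured volume (MV) with
    diameter-derived estimated volume (EV) of solid pulmonary nodules in
    low-dose CT lung cancer screening. Classifies nodules into screening
    outcome categories from volume thresholds, computes volume doubling
    times (VDT) and their categories, cross-tabulates MV- versus EV-based
    categories at nodule and screenee level, quantifies agreement with
    weighted Cohen's kappa (unweighted, linear, quadratic weights),
    measures severity shift among discordant classifications, and
    simulates the recall burden (number of scheduled follow-up scans)
    under each measure. Ships published-style cross-classification
    fixture tables and a seeded synthetic-cohort generator so the full
    pipeline is testable without restricted trial data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
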