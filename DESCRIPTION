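Package: clcoupling
Title: Cardiac-Locomotor Coupling Analysis for Wearable Heart-Rate and Step Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects minute-level cardiac-locomotor coupling (CLC) in
    free-living wearable recordings. Aligns 5-second heart-rate samples with
    per-minute step counts, computes the coupling ratio R = SR/HR, classifies
    coupling strength (CLC, weak CLC, no CLC) and cadence-based activity
    intensity, segments activity bouts, and contrasts the observed R
    distribution against an exact random-pairing null. Includes the
    nonparametric tests and effect sizes used in wearable coupling studies
    (Wilcoxon signed-rank with r = |Z|/sqrt(N), Kruskal-Wallis with eta
    squared, Friedman), per-subject and cohort reporting, and a seeded
    synthetic cohort generator with ground-truth entrainment labels for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
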