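Package: pairqpcr
Title: Pairwise Efficiency Estimation for qPCR Dilution Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates real-time PCR amplification efficiency from all pairwise
    combinations of baseline-subtracted fluorescence readings across a dilution
    series, with histogram-frequency outlier exclusion, alongside the classical
    calibration-curve estimator. Includes exponential-phase window diagnostics
    (noise profiling, first-outlier takeoff detection, first-derivative maximum,
    boundary grid search), a Monte-Carlo precision harness for comparing
    estimators on replicate dilution sets, downstream relative quantification
    (initial-fluorescence back-calculation and efficiency-corrected expression
    ratios), and a seeded synthetic-plate simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
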