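Package: stsfrailty
Title: Digital Frailty Biomarkers from Sensor-Based Sit-to-Stand Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts seventeen biomechanical features (duration, joint
    angle, angular velocity, angular and vertical power ranges and their
    cycle-to-cycle coefficients of variation) from five-times sit-to-stand
    motion recordings, screens them for robust versus pre-frail/frail
    group differences with normality-routed tests, ranks them by
    bootstrapped recursive feature elimination over logistic models scored
    by out-of-bag validation AUC, selects the minimal subset covering the
    slowness, weakness and exhaustion frailty phenotypes, and evaluates
    classification performance with bootstrap confidence intervals.
    Includes a seeded synthetic-cohort generator with closed-form
    kinematic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
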