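Package: stressemm
Title: Additive Effect-Measure Modification of the Stress-Oral Health
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing effect measure modification on the
    additive scale in cross-sectional survey data: dichotomization of
    categorical survey responses into binary exposures and a composite
    oral-health outcome, adjusted prevalence-ratio estimation by
    log-binomial regression with a robust-variance modified-Poisson
    fallback, joint-exposure prevalence ratios within age strata, the
    relative excess risk due to interaction (RERI) with delta-method and
    bootstrap confidence intervals, the attributable proportion, and
    Knol-VanderWeele presentation tables. Includes a synthetic
    survey-data generator with closed-form truth for validation, a
    reconstruction of record tables from published cell counts, and a
    verifier for published worked examples.
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
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
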