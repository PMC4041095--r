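Package: harmsurvey
Title: Point-Prevalence Harm Survey Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running monthly point-prevalence patient-safety
    surveys across the four classic nursing-sensitive harms (pressure
    ulcers, falls, catheter-associated urinary tract infection proxy,
    venous thromboembolism). Provides a validated patient-level record
    schema with cross-field rules, the published measure catalogue and the
    "harm-free care" composite, hierarchical merge and ward-to-national
    rollup, exact binomial confidence intervals and proportion
    comparisons, run charts and variable-denominator p-charts with
    attribute-chart sample-size planning, and a configurable synthetic
    cohort generator so every analysis is testable without real patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
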