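Package: riskcalib
Title: Hierarchical Condition Category Risk Scoring and Decile Calibration
    for Dual-Payer Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Specification-driven hierarchical condition category (HCC) risk
    scoring of patient-year claims, a 47-category psychiatric case-mix
    grouper, cost regressions (ordinary least squares, square-root OLS with
    Duan smearing, and gamma log-link GLM), and decile-of-predicted-cost
    calibration tables for full cohorts and clinical subgroups (diabetes,
    mental health, dementia). Includes a deterministic dual-payer synthetic
    claims generator with known ground truth and configurable psychiatric
    under-pricing, so the whole analysis pipeline is testable end to end,
    plus a missed-psychiatric-diagnosis analysis contrasting a 4-category
    risk model with the 47-category grouper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
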