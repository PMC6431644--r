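Package: pirisk
Title: Claims-Based Risk Vital Sign Screening for Primary Immunodeficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a weighted infection-claims point score (the "Risk Vital
    Sign") that flags health-plan members at elevated risk of primary
    immunodeficiency (PI) from administrative diagnosis and pharmacy claims.
    Implements the full population-screening workflow: ICD-9/ICD-10 code
    weighting with longest-prefix matching, episodic exceptions for otitis
    media and sinusitis, a continuous-antibiotic-therapy rule over merged
    days-supply intervals, risk categorization, prior-PI exclusion,
    medium-high-risk cohort extraction, twelve-month follow-up re-analysis
    (new PI and concerning-diagnosis tallies), demographics tables, and a
    cost-savings estimate. A synthetic-claims generator with planted risk
    phenotypes and a ground-truth file makes every pipeline stage testable
    without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
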