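Package: riskconcord
Title: Concordance of Cardiovascular Risk Scores in Complex Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores individuals with three 10-year cardiovascular risk
    equations (the Framingham general cardiovascular disease score, the 2018
    logistic revision of the Pooled Cohort Equations, and a country-recalibrated
    Globorisk-type laboratory equation), harmonizes national-health-survey style
    records into analysis-ready risk-factor profiles with explicit imputation
    and eligibility rules, and quantifies between-score agreement two ways: a
    fold-ratio (log-scale Bland-Altman window 0.8-1.25) concordance of the
    continuous risks, and the survey-weighted Gwet first-order agreement
    coefficient (AC1) over guideline risk strata. Includes a seeded Gaussian
    copula generator for synthetic survey populations so the whole pipeline is
    testable without microdata downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
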