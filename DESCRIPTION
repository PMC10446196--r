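Package: surveyguard
Title: Points-Based Fraud Screening for Incentivized Online Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fraudulent submissions to incentivized web surveys. Implements a
    two-stage eligibility screen (zip-to-county validation, CAPTCHA and speed-bump
    gates, honeypot and client/server time-zone checks), a points-based fraud-scoring
    engine with per-indicator detectors (infeasibly short completion times, duplicate
    hashed IPs and contact details, unusual email formats, inactive recruitment
    sources, cross-form inconsistencies, duplicate or near-duplicate open text,
    simultaneous geographic matches, identical-response clusters, and wave-patterned
    submission timing), and a seeded simulator that generates labelled synthetic
    cohorts of legitimate respondents, professional survey takers, and bots for
    validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
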