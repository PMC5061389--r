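Package: crcdemand
Title: Microsimulation of Colonoscopy Demand in FIT-Based Colorectal
    Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event microsimulation of a population-based
    colorectal cancer screening program using the fecal immunochemical
    test (FIT), with post-polypectomy surveillance following European
    guideline intervals. Forecasts yearly demand for colonoscopies
    (after a positive FIT and for surveillance) over a 20-year horizon
    in a dynamic population of 100,000 inhabitants aged 50-69, runs a
    probabilistic multivariate sensitivity analysis over replicated
    simulations, filters replications to a current-scenario subgroup,
    and fits a linear regression meta-model of demand drivers
    (participation, FIT positivity, surveillance adherence) with time
    interactions. Includes a synthetic screening-registry generator and
    the matching stratified parameter estimator, closing the
    calibration loop without person-level program data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
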