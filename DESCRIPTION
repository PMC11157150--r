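Package: accbehav
Title: Behaviour Classification and Heat-Response Time Budgets from
    Collar Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning raw tri-axial collar accelerometer bursts
    into behaviour-specific time budgets and energy-expenditure proxies
    for free-ranging ungulates. Covers burst ingestion and validation,
    centring and collar-orientation harmonisation, time- and
    frequency-domain burst features including overall dynamic body
    acceleration (ODBA), correlation-filtered forward feature selection,
    gradient-boosted behaviour classification with cross-validated
    confusion reports, ethogram consolidation, blackglobe heat-index
    computation, hottest and coolest day selection, time-budget and
    mean-ODBA aggregation, and penalized-spline mixed models for
    afternoon heat responses and hot versus cool day diel activity
    curves. A synthetic-data module generates labelled bursts, behaviour
    timelines and weather series with known ground truth so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    rlang,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
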