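Package: peatfire
Title: Peatland Hydrology Simulation and Hydrology-Informed Fire Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates daily water table depth and near-surface soil moisture for
    stand-alone tropical peat and mineral soil columns with a layered
    tipping-bucket water balance (van Genuchten retention, Mualem conductivity,
    Penman-Monteith-style reference evapotranspiration, and lateral Darcy
    exchange with a boundary water table), aggregates daily output to
    fortnightly predictor records, and trains parallel weather-only and
    weather-plus-hydrology neural-network fire-count regressors with
    leave-one-year-out cross-validation. Includes evaluation metrics
    (pooled R-squared, MAE, time-differenced skill, Youden-J water-table fire
    threshold estimation) and a seeded synthetic-data generator emulating a
    bimodal-dry-season tropical peatland province so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
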