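Package: exodeplete
Title: Substrate-Depletion Kinetics and Co-Culture Prediction from
    Exometabolomic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing time-resolved exometabolomic (metabolic
    footprinting) experiments in which microbial monocultures deplete a
    defined mixture of substrates. Fits per-species substrate-depletion
    time courses to a four-parameter decreasing logistic, derives
    substrate-preference metrics (half-depletion time, usage window,
    maximum depletion rate per gram cell dry weight), converts LC-MS peak
    areas to absolute concentrations via internal-standard-normalised
    calibration curves, predicts the substrate depletion of a multi-species
    co-culture by combining the individual models under a shared finite
    resource pool (capping and refitting), and scores observed co-culture
    data against the prediction to flag compounds whose use deviates from
    blind sharing. Includes a synthetic-data generator and a brute-force
    shared-pool consumption simulator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
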