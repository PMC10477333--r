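Package: soccf
Title: Counterfactual Attribution of Cropland Management Effects on Soil
    Organic Carbon Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A survey-based counterfactual pipeline for attributing national
    soil organic carbon (SOC) stock changes in cropland mineral soils
    (0-30 cm) to individual climate-smart practices. Simulates SOC
    trajectories with a multi-pool daily-step soil carbon model over a
    weighted survey of cropland locations, imputes management histories
    (marginal-constrained Markov-chain tillage, predictive mean matching for
    nitrogen inputs, hot-deck cover crops with a linear adoption ramp),
    removes practices one at a time, and propagates three sources of
    uncertainty (imputation, model structure via a linear mixed-effect bias
    model, and survey scaling via delete-a-group jackknife replicate
    weights) into national annual stock-change estimates with confidence
    intervals and inverse-distance-weighted effect maps. A synthetic-data
    module generates every input the pipeline needs, so the full analysis is
    testable without confidential survey microdata.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
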