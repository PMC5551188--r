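Package: lurf
Title: Land-Use Random Forests for Fine-Scale Urban NO2 and Respiratory
    Health Impact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking urban land use and land cover to fine-scale
    ambient nitrogen dioxide (NO2) and its respiratory health consequences.
    Provides a synthetic-city generator with a known NO2-generating process,
    circular-buffer land-use feature extraction, a two-phase land-use random
    forest (LURF) with conditional permutation importance and a stepwise
    land-use regression (LUR) baseline, model evaluation metrics, 200 m
    prediction surfaces, counterfactual category-zeroing attribution,
    land-use modification sensitivity analysis with proportional
    rebalancing, and log-linear concentration-response health impact
    functions with areal-weighted population allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
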