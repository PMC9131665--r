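Package: peckyrice
Title: Landscape-Based Prediction and Hazard Mapping of Pecky Rice Damage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A spatially explicit pipeline for predicting pecky rice damage
    caused by the sorghum plant bug from surrounding land use. Extracts
    land-use composition within a 300-m buffer of research points (with a
    field-margin correction), carries the published original and extended
    random-intercept mixed-model prediction equations, refits and ranks
    candidate models by REML/AICc with variance-inflation checks, evaluates
    predictions against the Japanese brown-rice grade thresholds
    (confusion statistics, ROC/AUC, three-fold cross-validation), and maps
    priority areas on a 300-m hexagon grid. Includes a synthetic-landscape
    generator emulating the three study regions so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    stats,
    tibble,
    utils,
    withr
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
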