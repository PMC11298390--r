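Package: scfsol
Title: Correlating Drug Solubility in Supercritical CO2 with Metaheuristic-Tuned Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models mole-fraction solubility of a drug (ketoprofen) in
    supercritical carbon dioxide as a function of temperature and pressure.
    Implements three regression families - piecewise polynomial regression with
    CART-like axis-aligned partitioning, kernel ridge regression via the
    closed-form dual solve, and a Tweedie power-variance generalized linear
    model fitted by iteratively reweighted least squares - with hyperparameters
    tuned by a Water Cycle Algorithm metaheuristic minimizing cross-validated
    RMSE and filtered by AIC. Includes a synthetic solubility-surface generator
    (exponential in temperature, linear in pressure, lognormal noise) for
    parameter-recovery and overfit-guard experiments, evaluation metrics, trend
    analysis, and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
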