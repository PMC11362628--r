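Package: pexfair
Title: Group-Fairness Audit of Pulmonary Exacerbation Prediction in Cystic Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit a precision-medicine algorithm that forecasts
    pulmonary exacerbations (PEx) in cystic fibrosis for racial and ethnic
    group fairness. Implements the FEV1-indicated exacerbation signal (FIES)
    labeling rule, a linear mixed model with a continuous-time integrated
    Brownian motion stochastic process for longitudinal FEV1 percent
    predicted, conditional Gaussian forecasting of exacerbation risk over
    3-, 6-, and 12-month horizons, group-stratified ROC evaluation with
    Youden-index cutoffs and stratified bootstrap confidence intervals,
    predictor-by-group association screening, and a synthetic patient
    registry generator that emulates the longitudinal encounter structure of
    a CF patient registry so the whole audit runs end to end without access
    to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
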