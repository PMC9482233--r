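Package: pcmval
Title: Partial Credit Model Estimation and Construct-Validation Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional maximum likelihood estimation of the partial credit
    model for polytomous questionnaire data, together with the diagnostic
    toolkit used in Rasch-based construct validation: standardized response
    residuals, item and person fit residuals, class-interval item chi-square
    tests, threshold-ordering checks with the Salzberger hybrid test,
    residual-correlation screening for local dependency, principal component
    analysis of residuals with Smith's unidimensionality t-test, differential
    item functioning by two-way analysis of variance of residuals, testlet
    (super-item) analysis with variance decomposition and disattenuated
    latent correlations, person separation reliability, and descriptive
    scoring for the 23-item Burnout Assessment Tool, whose scale definition
    and a published threshold calibration ship as simulation defaults.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
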