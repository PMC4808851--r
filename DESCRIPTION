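Package: biaffm
Title: Validation and Development of Bioimpedance Fat-Free Mass Equations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating bioelectrical impedance analysis (BIA)
    prediction equations of fat-free mass against a dual-energy X-ray
    absorptiometry (DXA) reference, and for developing population-specific
    equations. Provides an evaluable catalogue of published single-frequency
    (50 kHz) FFM equations, the full method-agreement statistics suite
    (Bland-Altman limits of agreement with trend test, Lin's concordance
    correlation with its precision/accuracy decomposition, pure error,
    standard error of estimate, technical error of measurement), a
    development/cross-validation pipeline based on a random 2:1 split and
    p-value stepwise regression, and a synthetic anthropometric cohort
    generator for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
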