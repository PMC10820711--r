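Package: nirvol
Title: Chemometric Roast-Degree Classification and NIR-Based Prediction of
    Coffee Volatiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Latent-variable chemometrics for monitoring coffee roasting.
    Classifies roast degree (light, medium, dark) from GC-MS volatile
    peak-area tables and from near-infrared (NIR) diffuse-reflectance
    spectra using NIPALS partial least squares discriminant analysis with
    venetian-blinds cross-validation; selects discriminant volatiles with
    the variable identification (VID) correlation statistic; and predicts
    individual volatile abundances from NIR spectra with per-compound PLS
    regression under cross-origin validation (R-squared and NRMSEP
    scoring). Includes extended multiplicative signal correction (EMSC)
    for scatter artifacts, peak-table abundance and reproducibility
    filters, and a synthetic-data generator that emulates the roast-trend
    and scatter structure of the real measurements so the whole pipeline
    is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
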