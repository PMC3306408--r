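Package: hormfit
Title: Hormetic Dose-Response Models with Directly Estimable Effective Doses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Brain-Cousens and Cedergreen-Ritz-Streibig (CRS)
    hormetic modifications of the four-parameter log-logistic dose-response
    model by weighted nonlinear least squares, and reparameterizes both
    families so that the effective doses ED_K, the limited dose for
    stimulation (LDS), and the dose of maximal stimulation (M) become model
    parameters with standard errors and Wald/t confidence intervals.
    Includes the confidence-interval test for the significance of hormesis,
    delta-method prediction of the maximal response y_max, quantification of
    a pre-hormetic drop (M_min, y_min, LDS_min), lack-of-fit and pseudo-R2
    diagnostics with a four-case model-comparison report, and Monte-Carlo
    harnesses (synthetic-data generator, coverage, type-I error, and
    model-misspecification experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
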