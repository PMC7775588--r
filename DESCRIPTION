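Package: indirectci
Title: Confidence Intervals for Indirect Effects in Mediation Models with
    Nonnormal Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point and interval estimation of unstandardized and completely
    standardized indirect effects in simple and serial mediation path models.
    Implements five interval procedures: the nonparametric percentile
    bootstrap, profile likelihood-based confidence intervals under
    normal-theory maximum likelihood, under asymptotically distribution-free
    (ADF) estimation, and with the predictor variance fixed, and the Monte
    Carlo (parametric simulation) interval. Includes a data generator for
    mediation populations with nonnormal predictors and conditionally normal
    errors, and a coverage-probability simulation framework with tidy results
    tables and plots.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
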