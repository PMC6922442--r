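Package: emci
Title: Simultaneous Confidence Intervals for Ensemble Modeling Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Statistical inference for populations of kinetic-model outputs
    such as flux control coefficients from metabolic control analysis.
    Builds univariate and simultaneous confidence intervals for many
    variables at once (Bonferroni, exact-normal via the equicoordinate
    quantile of a correlated multivariate normal, and balanced bootstrap
    with pre-pivoting and tail balancing), compares multiple model
    ensembles through globally corrected mean-difference intervals,
    computes Bonferroni sample sizes for a target margin of error, and
    ships known-truth synthetic generators (a toy metabolic network with
    sampled elasticities, and Gaussian-copula ensembles with skewed
    marginals) together with a coverage-simulation harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
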