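Package: rmasim
Title: Simulation of Repeated-Measures Analyses Under Covariance Misspecification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates balanced longitudinal body-weight experiments (three
    dietary treatment arms measured at five weeks) from a published parameter
    table, fits the saturated treatment-by-time cell-means model by restricted
    maximum likelihood under heterogeneous or homogeneous compound-symmetry and
    first-order autoregressive residual covariance structures, runs separate
    per-week one-way ANOVAs, and summarises type I error, power and
    standard-error-of-the-mean behaviour across a factorial grid of sample
    sizes and within-subject correlations. Quantifies how assuming a constant
    variance over time distorts per-time treatment tests when the true
    variance grows with time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    pracma,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
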