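Package: symmsel
Title: Symmetry-Based Model Selection for Age-Incidence Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting between mechanistic models of cancer
    incidence as a function of age using one-parameter Lie symmetries.
    Implements the power law (multistage carcinogenesis) and immunological
    (immunosenescence) risk models, their closed-form symmetry
    transformations, orthogonal distance regression with the RMS
    statistic, and the transform/fit/inverse-transform/score selection
    loop, together with a synthetic-data generator for in silico
    benchmarking and numeric verifiers (linearized symmetry condition,
    reduced characteristic, flow exponentiation) for the symmetries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
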