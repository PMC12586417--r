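Package: corsm
Title: Continuous Rating Scale Model Estimation for Visual Analogue and
    Likert Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Mueller's continuous rating scale model (CoRSM), a
    Rasch-family item response model for bounded continuous responses such
    as visual analogue scale (VAS) marks, in which each response follows a
    doubly truncated normal distribution on the response line. Item
    difficulties are estimated by marginal maximum likelihood with Gauss
    quadrature, person abilities by maximum a posteriori estimation, and
    the dispersion parameter by maximum likelihood, alternating to joint
    convergence. Likert-type (discrete) data are supported through the
    equivalence between the discretised CoRSM and the rating scale model
    with equidistant thresholds. Includes response simulators (truncated
    normal and rating scale model), Fleishman non-normal ability
    generation, a Monte Carlo parameter-recovery harness, outfit mean
    square fit statistics with an item-retention rule, a split-sample
    stability check, and a command-line interface for wide-format rating
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
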