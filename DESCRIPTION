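Package: crabdeb
Title: Dynamic Energy Budget Simulation of Molt-Driven Crustacean Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based bioenergetic simulation of non-continuous,
    biphasic growth in pond-cultured swimming crabs. Implements a dynamic
    energy budget (DEB) model with a carbon-to-wet-weight (alpha) molting
    trigger, stage-segmented kappa allocation, and a demand-driven ovarian
    development module, together with temperature forcing utilities
    (Arrhenius correction, seasonal profiles), parameter estimators for the
    supporting physiological experiments, goodness-of-fit statistics,
    one-at-a-time parameter sensitivity analysis, and synthetic-data
    generators for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
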