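Package: oystergrowth
Title: Decoupling Harvest Pressure from Growing Conditions in
    Archaeological Oyster Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for size demography of archaeological shell middens:
    von Bertalanffy growth modelling of oyster hinge size at
    sclerochronological age, per-shell growth residuals that separate
    environmental growing conditions from age-at-harvest, empirical
    hinge-to-length conversion, nonparametric period and site
    comparisons with Bonferroni correction, relative-weights
    partitioning of shell-size control between age and growth rate,
    stratigraphic layer sequences, and a scenario-driven synthetic
    assemblage generator for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
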