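Package: colonyfit
Title: Selection Coefficients from Colony-Size, Growth-Curve and
    Flow-Cytometry Fitness Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-generation relative fitness (selection
    coefficients) of microbial strains from colony sizes pinned at high
    density on agar plates, with the companion liquid growth-curve and
    flow-cytometry competitive-fitness pipelines used to validate such
    estimates. Includes a size-to-cell-number calibration with day-0
    anchoring, concentric-layer edge-effect diagnostics and row/column
    normalization, snake-randomized plate layouts, growth-parameter
    extraction from OD600 time series, ellipse gating and false-negative
    correction for marked-reference competitions, power analysis for
    fitness differences, and seeded synthetic-data generators for all
    three assay types.
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
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
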