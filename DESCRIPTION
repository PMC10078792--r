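Package: growthdom
Title: Growth Partitioning Analysis for Repeated Forest Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the growth dominance coefficient (a Lorenz-curve
    statistic on cumulative proportional tree size versus cumulative
    proportional tree growth) and the size-growth relationship slope from
    repeated forest inventory data, and provides the surrounding analysis
    pipeline: a seeded synthetic stand and inventory-series generator for
    even-aged and single-tree-selection structures, subsampling and
    size-range sensitivity experiments, a nested-plot drought analysis with
    linear mixed-effect models and Tukey contrasts, and site/climate
    covariate modelling with Thornthwaite potential evapotranspiration,
    collinearity screening and AICc model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
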