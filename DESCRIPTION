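Package: navcea
Title: Early Cost-Effectiveness Analysis of Image-Guided Navigation
    Surgery for Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of image-guided navigation surgery
    versus standard surgery for locally advanced (LARC) and locally recurrent
    (LRRC) rectal cancer. Combines a resection-margin decision tree with a
    three-state Markov cohort model with tunnel states (three-month cycles,
    three-year horizon, Dutch healthcare perspective) to estimate discounted
    costs, QALYs and life-years per strategy and the incremental
    cost-effectiveness ratio. Includes probabilistic sensitivity analysis with
    cost-effectiveness planes and acceptability curves, one-way deterministic
    (tornado) sensitivity analysis, scenario and threshold analyses on the
    navigation cost, expected value of perfect and partial perfect information,
    and a synthetic patient-level cohort generator for end-to-end parameter
    recovery testing. All model inputs are supplied as YAML parameter files;
    configurations for both indications are shipped with the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
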