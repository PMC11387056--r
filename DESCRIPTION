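Package: localadapt
Title: Selection Analysis for Reciprocal Transplant Experiments with Soil Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify local adaptation from fully crossed site x soil x
    ecotype reciprocal transplant experiments. Computes per-treatment-cell
    fitness components (survival to reproduction, fecundity, seeds per fruit,
    and a multiplicative overall-fitness proxy), selection coefficients against
    the non-local ecotype with stratified bootstrap confidence intervals, and a
    within-site soil-permutation test of whether selection differs between soil
    types. Includes a synthetic cohort generator with known true selection
    coefficients and a Monte Carlo power-analysis layer, so the entire pipeline
    can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    yaml,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
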