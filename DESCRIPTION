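Package: dietscape
Title: Zip-Code-Level Food Environment and Diet Outcome Analysis via
    Genetic Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An observational-analysis pipeline relating zip-code-level
    food environment (grocery and fast-food access), median family income
    and college education to diet outcomes derived from smartphone food
    journals: rule-based classification of free-text food-log entries into
    fresh fruit & vegetable, fast food and non-diet soda categories;
    multi-level aggregation to participant and zip-code outcome measures;
    population-weighted census-tract-to-zip food-environment covariates;
    median-split treatment assignment with one-to-one genetic matching with
    replacement, standardized-mean-difference balance diagnostics and an
    adaptive caliper; and average-treatment-effect-on-the-treated
    estimation with matched-pair bootstrap confidence intervals, plus
    null-treatment and subgroup experiment runners. Includes a synthetic
    data generator with known ground-truth effects for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rlang,
    dplyr,
    tibble,
    tidyr,
    stringr,
    readr,
    jsonlite,
    yaml,
    geosphere,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
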