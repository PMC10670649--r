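Package: fpromethee
Title: Fuzzy-PROMETHEE Outranking Analysis for Diagnostic Test Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native implementation of the fuzzy PROMETHEE
    multi-criteria decision analysis workflow used to rank diagnostic
    tests: linguistic weighting with triangular fuzzy numbers, Yager
    centroid defuzzification, Gaussian (and standard-catalogue) pairwise
    preference functions, leaving/entering/net outranking flows,
    PROMETHEE I partial and PROMETHEE II complete rankings, unicriterion
    flow profiles, and criterion-omission sensitivity analysis with
    Kendall rank correlation. Ships the 16-alternative by 15-criterion
    urinary-tract-infection diagnostic study design as a built-in
    replica, together with a seeded synthetic decision-matrix generator
    that stands in for the study's unpublished expert evaluations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
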