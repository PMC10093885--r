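Package: novamed
Title: NOVA Classification, FSAm-NPS Nutrient Profiling and Mediterranean
    Diet Pyramid Mapping for Branded Foods
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for food-level analysis of branded (packaged) food
    composition data: assignment of products to the four NOVA food-processing
    groups from free-text ingredient lists using a configurable marker
    lexicon; computation of the FSAm-NPS nutrient-profiling score and the
    five-letter Nutri-Score grade with explicit missing-data exclusion and
    imputation rules; eligibility screening and tier assignment for the
    traditional and sustainable Mediterranean diet pyramids; nonparametric
    group-comparison summary tables (median and interquartile range,
    Kruskal-Wallis and Mann-Whitney tests with Bonferroni correction); and a
    synthetic branded-food database generator with ground-truth labels for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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
    withr
Config/testthat/edition: 3
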