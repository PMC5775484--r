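Package: cob12
Title: Dietary Vitamin B12 Intake Proxies from Web Search Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology studies that use recipe search patterns
    as a proxy for dietary vitamin B12 intake. Provides a seeded synthetic
    search-log generator with known ground truth, query processing (recipe
    matching, medical-term matching, B12-awareness classification, per-user
    aggregation), per-user B12 consumption scores with group contrasts and a
    regional expenditure validation, per-term linear probability models with
    the CoB12 coefficient-content correlation, and an R2I-weighted
    rank-regression meta-model relating CoB12 to drug indication breadth.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
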