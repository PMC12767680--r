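Package: etscan
Title: Prevalence and Co-Occurrence of Emulsifiers, Thickeners and
    Stabilizers in Packaged-Food Markets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping food additives of the emulsifier, thickener
    and stabilizer class (E-numbers E400-E499) across tabular packaged-food
    product databases. Detects additives in free-text ingredient lists with
    a curated regular-expression lexicon, applies eligibility and
    deduplication filters to raw product records, classifies products as
    hyper-palatable from declared nutrition, and quantifies additive
    co-occurrence by fold enrichment with exact two-sided p-values (Blaker's
    method on a chained multiset-hypergeometric null) and bootstrap
    percentile intervals of log fold enrichment. Includes a seed-reproducible
    synthetic market generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
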