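Package: nbudgetr
Title: Cropland Nitrogen Budget Accounting for Country-Year Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble soil-surface nitrogen (N) budgets for cropland
    from country-year panel statistics: crop-category N harvests with
    consistent area/harvest estimators, fodder-crop gap filling and dry-matter
    harmonization, allocation of synthetic fertilizer between cropland and
    permanent grassland from sparse survey data, manure N flows from excretion
    through storage losses to field application with exact conservation,
    symbiotic N fixation, and atmospheric deposition. Includes a seeded
    synthetic-data generator that emulates the statistical structure of
    FAOSTAT/Eurostat-style inputs (missingness, lumped fodder categories,
    mixed humidity bases, sparse fertilizer surveys) so every stage has a
    recovery test that needs no external downloads.
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
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
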