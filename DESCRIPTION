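Package: eatkit
Title: Curation Toolkit for Food-Composition Databases Underpinning Dietary
    Assessment Apps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a national food-composition reference (AUSNUT
    2011-13 style: 8-character hierarchical food codes, per-100 g nutrient
    panels, companion household-measure file) into the food database behind a
    mobile dietary-assessment app. Covers reason-coded removal of foods with an
    auditable ledger, merging of nutritionally similar foods within a minor
    category under a symmetric per-nutrient tolerance, integration of branded
    ready-to-eat chain menu items carrying label-only nutrient panels,
    household-measure to gram and millilitre portion derivation, a
    deterministic tiered food-name search engine (keyword shortlists,
    exact-name priority, whole-word and substring tiers, hyphen, apostrophe
    and ampersand normalisation), an append-only food diary model with a
    3 a.m. logging-day reset, System Usability Scale scoring, and a seeded
    synthetic-fixture generator with a ground-truth manifest for end-to-end
    testing.
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
    stringr,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
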