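Package: ewepref
Title: Participatory Trait-Preference Analysis for Pastoral Sheep Flocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing participatory livestock surveys in which
    farmers rank ewes within breed groups and give ordered reasons for their
    choices. Implements the weighted-reasons preference index per trait group
    and stratum, clustering of trait categories with renormalisation, across-
    breed rank rescaling and averaging, and fixed-effects linear models with
    nested farmer-within-site effects, type II tests, least-squares means and
    compact letter displays. Includes a synthetic flock-survey generator that
    emulates the study design so every pipeline stage is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
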