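Package: galgame
Title: Foraging-Game Analysis of Yeast GAL-ON/GAL-OFF Phenotype Mixes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven consumer-resource simulation and evolutionary
    game analysis of the yeast galactose-use decision. Models GAL-ON and
    GAL-OFF phenotypes competing for glucose and galactose in batch and
    serial-dilution culture, locates evolutionarily stable and
    growth-optimal phenotype mixes, computes competition-assay fitness
    statistics (absolute and relative fitness from optical density and
    strain fractions), estimates equilibrium frequencies by polynomial
    fitting with bootstrap confidence intervals, gates bimodal
    flow-cytometry-style fluorescence tables, and runs in-silico
    serial-dilution evolution experiments with mutation on the strategy
    parameter. Includes generators for synthetic competition records and
    cytometry event tables with known ground truth.
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
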