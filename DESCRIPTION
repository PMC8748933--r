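Package: antiherbiome
Title: Megafauna Herbivory Legacies in Neotropical Plant Defence Biogeography
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to link the history of extinct megafauna herbivores to the
    present-day geography of plant antiherbivory traits at the ecoregion
    scale. Implements abundance-weighted scaling of species traits to
    ecoregions, extinct and extant herbivore assemblage metrics from
    presence grids, wildfire and hurricane disturbance indicators, a
    regression protocol combining correlation screening, bidirectional
    stepwise AIC selection with significance pruning, Williams-type
    overdispersed binomial fits, effect sizes and dominance analysis, a
    species-by-ecoregion matrix randomization test, hierarchical clustering
    on principal components into antiherbiomes, and a rule-based detector of
    savanna-to-forest biome shifts validated against fossil sites. A
    synthetic world generator with planted effects makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    lmtest,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    car
Config/testthat/edition: 3
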