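Package: forestarch
Title: Expert Rule-Based Mapping and Assessment of Forest Archetypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies forest landscapes into seven archetypes (A-G) along a
    gradient of naturalness, protection and wood-production intensity using an
    expert decision-rule system over harmonized raster layers (forest mask,
    availability for wood supply, primary-forest features, IUCN protection
    categories, mean wood production). Provides the surrounding assessment
    toolkit: regional extent accounting and shares, Moore-neighbourhood patch
    delineation with mean patch size statistics, spatially thinned sampling
    with one-way ANOVA and Tukey HSD tests (single-shot and iterative
    resampled variants), 500-km latitudinal slice assessments in a Lambert
    azimuthal equal-area grid, threshold sensitivity sweeps, compositional
    benchmark agreement, and a seeded synthetic-landscape generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
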