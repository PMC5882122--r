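Package: lii
Title: Landscape Integrity Index Modeling for Regional Conservation Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a Landscape Integrity Index (LII) from three landscape
    indicators: a Human Influence Index composed of per-layer distance-decay
    intactness surfaces around mapped human land uses (roads, development,
    infrastructure, managed land cover), normalized terrestrial-vertebrate
    species richness from stacked binary habitat-suitability models, and
    normalized inverse vegetation departure. The three indicators are
    harmonized to a common 90-m grid, averaged with equal weights, and
    smoothed with a 1-km circular moving-window mean. Downstream
    conservation-planning tools derive a resistance surface from the index,
    map pairwise least-cost corridors between protected priority areas, select
    a corridor network covering a fixed fraction of unprotected land, and
    delineate high-integrity expansion areas adjacent to the existing
    protected-area network. A seeded synthetic-landscape generator supplies
    complete input sets (feature vectors, habitat stacks, departure fields,
    priority areas, ownership) with known ground truth, so the full pipeline
    runs and is testable without external geospatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    igraph,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
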