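Package: phyloendemix
Title: Spatial Phylogenetics of Endemism: Hotspots, CANAPE and Conservation Gaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based spatial phylogenetics for national-scale floras:
    taxonomic and range-weighted endemism (species richness, weighted and
    corrected weighted endemism), phylogenetic and relative phylogenetic
    endemism, CANAPE classification of neo-, paleo-, mixed- and
    super-endemism centres under marginal-preserving randomization nulls,
    percentile hotspot and coldspot mapping, Priority Hotspot intersection,
    protected-area gap analysis, climate-stability refugia, and spatial
    autoregressive error models of the environmental drivers of the
    metrics.  Includes a synthetic-landscape generator with planted,
    recoverable structure so the whole pipeline is testable without
    proprietary occurrence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
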