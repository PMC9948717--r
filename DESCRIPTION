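Package: betabef
Title: Beta Diversity, Community Assembly, and Ecosystem Functioning for
    Bacterioplankton Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether bacterioplankton beta diversity increases
    the summed biomass of paired communities, and whether that effect
    strengthens when deterministic assembly processes select for
    phylogenetically dissimilar taxa. Implements Bray-Curtis beta diversity
    on depth-standardized ASV count tables, the beta mean pairwise taxonomic
    index (a tip-shuffle null-model z-score of between-community mean
    pairwise phylogenetic distance), per-cruise and mixed-effects
    biodiversity-ecosystem-functioning regressions with backward covariate
    selection, a phylogenetic Mantel correlogram of habitat preferences, and
    a seeded synthetic-data generator with tunable assembly regimes and
    planted beta-diversity effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
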