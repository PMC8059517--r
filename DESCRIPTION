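Package: elevbeta
Title: Decomposed Taxonomic, Phylogenetic and Functional Beta-Diversity
    Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise incidence-based Sorensen dissimilarity and its additive
    decomposition into turnover and nestedness-resultant components, together
    with the phylogenetic (shared branch length, PhyloSor family) and
    functional (convex-hull overlap in a PCA trait space) analogues.
    Null-model standardized effect sizes under richness-preserving,
    fixed-fixed swap and label-shuffle randomizations; Blomberg's K
    phylogenetic signal; rank-sum comparisons of components, dimensions and
    species groups; distance-decay regressions along elevational distance with
    slope comparison and forward AIC selection of environmental predictors;
    and a seeded generator of synthetic elevational metacommunities with
    controlled turnover/nested geometry for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    grDevices,
    tools,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    jsonlite
Config/testthat/edition: 3
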