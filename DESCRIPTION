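Package: graftnet
Title: Network-Based Target Discovery for Vein-Graft Disease Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A target-discovery pipeline for time-resolved and multigroup
    vascular proteomics. Provides median normalization and ANOVA/FDR
    filtering of label-free protein abundances, coabundance trend
    clustering of kinetic profiles with a diagonal-covariance Gaussian
    mixture model, hypergeometric pathway enrichment with shared-protein
    pathway networks and centrality ranking, consensus prioritization of
    the most central pathway member proteins, and disease-module network
    proximity with degree-preserving randomization. Includes seeded
    synthetic-data generators (kinetic and static proteomes, scale-free
    interactomes, pathway collections and disease modules with planted
    ground truth) so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
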