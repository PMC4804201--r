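Package: epihost
Title: Host-Tree Trait Analysis of Atmospheric Bromeliad Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how host-tree functional traits drive the
    abundance and within-crown distribution of atmospheric (Tillandsia-type)
    bromeliads. Provides a validated data model for tree-level epiphyte
    censuses, community diversity metrics (Faith's phylogenetic diversity,
    dendrogram-based functional diversity, phylogenetic species
    variability/richness/evenness/clustering, Schoener co-occurrence),
    individual-randomization and tip-shuffle null models with quantile
    envelopes, a from-scratch hierarchical-partitioning engine with a
    permutation z-test, a recursive trait-tree partitioning algorithm with
    host-pattern classification (best/worst/trunk/branches hosts), downstream
    association statistics (Poisson and binomial GLM contrasts, PCA of
    pattern assignments), and a synthetic-data generator reproducing the
    statistical structure such field studies assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    picante,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
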