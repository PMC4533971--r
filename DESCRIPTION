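Package: rsdnet
Title: Bipartite Network Analysis of Ecological Regime Shifts and Their
    Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of bipartite co-occurrence networks linking
    ecological regime shifts to their drivers. Provides incidence-matrix input
    with driver-name canonicalization, one-mode projections and co-occurrence
    statistics, a bipartite (four-cycle) clustering coefficient, NODF
    nestedness, degree-preserving null models (curveball trades and sequential
    importance sampling) with standardized effect sizes and empirical p-values,
    driver-category and management-scale aggregation, permutation homophily
    tests on weighted projections, Sorensen-Dice/Jaccard distances with
    average-linkage clustering and classical multidimensional scaling with
    permutation vector fitting, and a seeded synthetic-network generator with
    planted nestedness and attribute homophily for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
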