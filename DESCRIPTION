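Package: chronet
Title: Succession-Stage Detection and Co-Occurrence Network Analysis for
    Microbiome Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage succession analysis for microbiome chronosequence
    OTU tables: compositional transforms (relative abundance, centered
    log-ratio) and Aitchison convergence to a reference community; alpha
    and beta diversity with Kruskal-Wallis/Dunn, PERMANOVA and ANOSIM;
    consensus identification of discrete ecological stages from two
    independent clusterers with silhouette-based model selection;
    random-forest validation of the stages with stratified
    cross-validation and Gini-importance biomarker ranking; stage-wise
    Spearman co-occurrence network construction with dual
    correlation/FDR thresholds; Louvain modules, within-module degree
    and participation-coefficient keystone roles, and an Erdos-Renyi
    null-model modularity Z-score; targeted-attack robustness
    simulation of the largest connected component. A synthetic
    chronosequence generator with planted regimes, modules and hubs
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
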