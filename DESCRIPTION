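Package: oncotreevec
Title: Embedding and Clustering of Tumor Mutation Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised vector representations of rooted, node-labeled
    tumor mutation trees. Each tree is decomposed into a document of
    category-tagged vocabulary words (Weisfeiler-Lehman relabeled node
    neighborhoods, clonal co-occurrence and exclusivity pairs, root-child
    relations and label-free subtree structures) and embedded with a
    PV-DBOW negative-sampling model so that trees sharing evolutionary
    patterns are close in cosine space. Includes cosine-distance
    hierarchical clustering with a maximum intra-cluster distance cutoff,
    silhouette-based parameter recommendation, dominant-pattern cluster
    interpretation, synthetic benchmark cohort generators and rank-order
    evaluation statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
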