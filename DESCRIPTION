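Package: profnet
Title: Disease-Profile Network Analysis for Drug Repurposing Candidate Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a disease-profile network from a heterogeneous biomedical
    knowledge graph and a seed cluster of related diseases by taking the union
    of radius-limited ego graphs, contracts nodes joined by cross-resource
    equivalence predicates into merged concepts with synonym-filtered labels,
    partitions the contracted network into modularity classes with the Louvain
    algorithm, scores each class with a per-community modularity score, computes
    five node centralities (degree, closeness, betweenness, eigenvector,
    PageRank) within each class, and ranks drug repurposing and repositioning
    candidates by a Total Normalized Centrality Score (TNCS). Includes a
    synthetic knowledge-graph generator with planted equivalence components,
    planted community structure and planted hub nodes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
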