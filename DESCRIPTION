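Package: netpharm
Title: Network Pharmacology Analysis of Compound-Target-Disease Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for network-pharmacology studies of multi-compound
    interventions (for example herbal preparations) against one or more
    diseases. Assembles a heterogeneous compound-target-disease interaction
    network from putative-target predictions, known therapeutic-target lists
    and a protein-protein interaction edge list; computes degree, betweenness,
    closeness and k-core centralities from scratch; identifies key targets by
    a two-stage median-threshold filter; partitions putative and disease
    target sets into Venn regions; performs hypergeometric over-representation
    analysis of the key targets against pathway gene sets with
    Benjamini-Hochberg correction and builds the pathway-target bipartite
    network; filters docking-score tables at the score median and builds the
    target-compound network. A seeded synthetic-data module generates complete
    input bundles with planted ground truth so every stage is testable
    offline. Networks are exported as SIF, GraphML or TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
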