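Package: distinctmods
Title: Discovery of Network-Specific Functional Modules in Labeled
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Graph-theory pipeline for discovering functional modules that are
    unique to one of a set of labeled protein-protein interaction networks.
    Networks are partitioned with a restricted-neighbourhood-search clustering
    (tabu-assisted local search over a naive and a scaled misclassification
    cost), modules are reduced to distinct subgraphs via canonical adjacency
    labels and edge-set enclosure, and distinct subgraph patterns are found
    with an edge-pattern index supporting both the greedy highest-degree
    matcher and an exact backtracking subgraph-isomorphism matcher. Includes
    minimum-subsumer Gene Ontology semantic scoring of patterns against random
    subgraph null draws, edge-overlap validation statistics against reference
    networks, a greedy sequence-identity clusterer for deriving node labels,
    and a seeded synthetic-ensemble generator with planted shared and unique
    modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
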