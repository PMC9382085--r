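Package: netpharm
Title: Network Pharmacology Core-Target Screening and Pathway Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for network-pharmacology inference on multi-compound
    herbal formulas: assembly of compound-target and disease-target evidence
    into tripartite herb-compound-target networks, two-group differential
    expression screening with multi-dataset Venn intersection, seed-plus-
    neighbour expansion of target sets against a protein-protein interactome,
    six topological centrality indices (degree, betweenness, closeness,
    eigenvector, local average connectivity, network centrality) with a
    two-stage median-multiple hub screen, and hypergeometric
    over-representation analysis with kappa-statistic grouping of enriched
    terms. A seeded synthetic-data module generates scale-free interactomes,
    planted differential-expression bundles, evidence tables and gene-set
    libraries so the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
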