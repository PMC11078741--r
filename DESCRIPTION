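Package: moninet
Title: Network-Based Integration of Transcriptomic and GWAS Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for network-based multi-omics integration of
    drug-response genetics: serial-filter differential expression of RNA-seq
    counts (TMM/CPM normalization, negative-binomial tests, Benjamini-Hochberg
    control), gene-based GWAS scoring (an LD-aware Monte-Carlo gene test plus
    network boosting of near-significant genes), random-walk-with-restart
    propagation of differential-expression seeds over a functional interactome
    with degree-matched permutation z-scores, hypergeometric overlap of the
    two evidence channels, and Louvain cluster / gene-set enrichment with
    hub-gene scoring. Ships a synthetic-data generator that plants a shared
    functional module across the omics layers so every stage is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    edgeR,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
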