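Package: mobdiv
Title: Repeat-Family Clustering and Clade Repartition Analysis of Low-Depth
    Sequencing Data, with an Allopolyploidy Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sample sequencing analysis (SSA) of genomic repeats:
    graph-based clustering of unassembled multi-species reads into repeat
    families under a sequence-identity threshold, cluster-by-species abundance
    matrices, top-cluster selection by cumulative read fraction, four-clade
    shared/exclusive (Venn) repartition, species correlation dendrograms, and
    neighbor-joining plastome trees with cytonuclear conflict metrics. Includes
    a synthetic-data generator that simulates ancestral mobilomes, ancient
    hybridization with maternal plastome inheritance, allopolyploidy, biased
    subgenome fractionation with transposable-element jump survival, and
    low-coverage paired-read sampling, so the whole pipeline is verifiable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    phangorn,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    callr
Config/testthat/edition: 3
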