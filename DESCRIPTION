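Package: dysbiosim
Title: Comparative Analysis of Gut Microbial Dysbiosis Signatures and
    Their Metabolic Pathway Completeness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An offline pipeline for comparative analysis of qualitative
    gut microbial dysbiosis records across diseases. Parses
    Disbiome-style exports of per-disease elevated/reduced taxon
    reports, compares disease signatures by multi-set (Venn)
    partitioning and pairwise overlap, builds common-taxonomy
    cladograms with Newick serialization, scores metabolic pathway
    completeness of genomes against a MetaCyc-style pathway panel
    (fraction of a pathway's reactions annotated in a genome), and
    clusters the resulting score matrices with feature auto-scaling,
    Euclidean distances and Ward agglomeration. Includes a synthetic
    data generator that plants known set overlaps and pathway scores so
    every stage is testable without live database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    ape,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
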