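Package: microko
Title: Comparative Microbiome Genomics via KO Paralog Enrichment,
    Genus Composition Clustering and 16S Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis toolkit for fecal-microbiome comparative genomics.
    Converts protein alignment hit tables into KEGG Orthology (KO) paralog
    count matrices, summarises them as per-genus medians, scores KO
    over-representation in a focal genus against background genera as a
    log2 fold-change of median copy numbers, and tests KEGG modules and
    pathways for enrichment with a one-sided Fisher's exact test. Also
    provides genus-composition processing for 16S amplicon count tables
    (coverage filtering, relative abundance, host averaging, top-N
    collapse, Euclidean hierarchical clustering), quality trimming and
    dereplication of amplicon reads, Kimura 2-parameter distances and
    neighbor-joining trees with outgroup rooting, and seeded synthetic-data
    generators (Poisson KO profiles with planted fold-changes,
    Dirichlet-multinomial communities, K2P sequence evolution on a known
    tree) for end-to-end recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    Biostrings,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
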