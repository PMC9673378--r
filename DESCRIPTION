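Package: orthodup
Title: Comparative Gene Duplication Profiling Across Chordate Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene orthogroups by duplication history in two
    lineages (e.g. amphioxus and vertebrates), separating small-scale
    duplicates from whole-genome-duplication ohnologs, and quantifies
    co-duplication enrichment between lineages with hypergeometric tests.
    Includes gene-tree monophyly validation of duplication calls, Gene
    Ontology annotation propagation and orthology transfer for functional
    parallelism analysis, expression specialization of duplicates
    (tissue-specificity Tau, union-of-duplicates condition deltas),
    synteny dotplots with tandem-duplication and chromosome-homology
    classification, gene-model evidence filtering, and a synthetic data
    generator with recoverable parameters for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
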