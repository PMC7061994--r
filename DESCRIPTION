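Package: xenoTE
Title: Transposable Elements and the Transcriptional Response to Insecticide Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for identifying transposable-element (TE)
    insertions that plausibly contribute to the transcriptional response to an
    insecticide in Drosophila strains. Includes negative-binomial differential
    expression with median-of-ratios normalization, TE-gene proximity and
    enrichment analysis, protein-protein interaction hub ranking by Maximal
    Clique Centrality, ATAC-seq reproducible-peak processing with an
    irreproducible discovery rate (IDR) filter and open/closed chromatin calls,
    cis-regulatory motif scanning, TE-family expression analysis, and a final
    evidence-integration ledger. A synthetic-data module generates every input
    with a planted ground truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
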