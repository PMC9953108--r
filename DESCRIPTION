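Package: tcscensus
Title: Genomic Census of Two-Component Signal Transduction Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rule-based identification and classification of two-component
    signal transduction proteins (histidine kinases, response regulators and
    phosphotransfer proteins) from per-genome domain annotations, followed by
    genomic-context organization (orphan/paired/complex clusters),
    domain-architecture and sensing-domain censuses, receiver/transmitter
    statistics, bidirectional-best-hit orthology with core/accessory
    partitioning, and parsimony-based gene gain/loss inference on a UPGMA tree
    derived from an average-nucleotide-identity matrix. Ships a synthetic
    genome-panel generator with machine-readable truth records so every stage
    of the pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
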