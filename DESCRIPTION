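Package: dscamtools
Title: Profile-HMM Block Scanning for Dscam-Family Genes and
    Hypervariable Exon Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects Dscam-family gene candidates in draft genome
    assemblies by building profile hidden Markov models from conserved,
    exon-boundary-free blocks of a protein alignment, calibrating their
    score null distributions, scanning six-frame translations of
    scaffolds, and calling candidates with an ordered k-of-n block
    co-occurrence rule. Block hits are chained into gene models, and
    intronic regions between constant-exon anchors are searched for
    tandem arrays of mutually exclusively spliced exon variants
    (including inverted copies). Includes a seeded synthetic-genome
    benchmark with planted genes, exon-variant arrays and truth
    annotations, plus codon back-translation and isoform-space
    arithmetic utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
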