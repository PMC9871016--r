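Package: mitorder
Title: Mitochondrial Gene Order, Codon Usage and Polycistronic
    Transcription Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of metazoan mitochondrial
    genomes: parsing and quality control of annotated mtDNA feature
    tables, signed circular gene-order algebra (anchoring, breakpoint
    distance, gene-cluster prevalence, alternating gene-block
    classification), a genome-architecture rate permutation test,
    relative synonymous codon usage versus mt-tRNA repertoire
    concordance testing, read-density comparison of same-strand versus
    different-strand gene-gene junctions in RNA-seq data, and
    transcription initiation/termination site detection from
    strand-specific nascent-RNA coverage. A synthetic-data generator
    produces gene orders, coding sequences, junction reads and coverage
    tracks with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
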