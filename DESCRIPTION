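Package: mitoscape
Title: Transcriptional Landscape Analysis of Plant Mitochondrial Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Strand-specific RNA-seq coverage analysis for plant
    mitochondrial genomes: genome-wide transcription statistics, per-gene
    RPKM, slope-based inference of transcription start sites and 3'
    transcript termini, coverage-based classification of co-transcribed
    gene pairs, and junction-read-based splicing efficiency of group II
    introns, together with a synthetic-data generator that produces
    annotated toy genomes, stranded coverage tracks and junction reads
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, Coverage, RNASeq, Annotation
RoxygenNote: 7.3.3
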