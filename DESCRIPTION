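Package: ernascan
Title: De Novo Discovery of Tissue-Specific Enhancer RNA Transcription
    from Strand-Specific RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies tissue-specifically transcribed intergenic regions
    (TSTRs) from strand-specific total RNA-seq of two tissues and
    characterizes them as candidate transcriptional enhancers. Implements
    sliding-window intergenic peak calling on 3'-extended read alignments,
    annotation filtering, differential transcription calling by the
    two-proportion z-test, RPKM, tissue-specificity and directionality
    indices, random-region background calibration with a 100-iteration
    normal fit, overlap with conserved elements, CAGE transcription start
    sites and p300/H3K27ac ChIP enrichment classes, strand-separated
    trimmed-mean coverage metaprofiles, z-scaled heatmap matrices, and
    binned correlation of TSTR tissue specificity with nearby gene
    expression. A seeded synthetic-data generator emulates the full input
    bundle (reads, annotation, feature tracks) with planted ground truth so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
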