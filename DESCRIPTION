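Package: cageAtlas
Title: Multi-Tissue CAGE TSS and Enhancer Atlas with Methylation Support
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a genome-wide atlas of transcription start sites (TSS)
    and divergently transcribed TSS-Enhancer loci from multi-tissue CAGE
    (Cap Analysis Gene Expression) 5' tag data. Tags are normalized to
    CAGE tags per million (CTPM), clustered uni-directionally into TSS and
    bi-directionally into promoter-proximal enhancer candidates, filtered
    by a cross-tissue representation rule, classified against gene-model
    regions (promoter, proximal, UTRs, exon, intron, intergenic), and
    labelled annotated or novel relative to known promoters. Novel TSS are
    corroborated with whole-genome bisulfite sequencing via a two-state
    Beta-Binomial hidden Markov model that segments hypomethylated
    regions. Tissue expression profiles are compared with a mutual
    information distance and hierarchical clustering. A fully specified
    synthetic tissue-panel generator with a machine-readable truth table
    supports end-to-end testing without external data.
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
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
biocViews: Transcription, GeneRegulation, Epigenetics, Sequencing,
    Annotation, Clustering
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
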