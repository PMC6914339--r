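Package: imprintTE
Title: Transposon-Distributed Transcription Factor Binding Sites and
    Genomic Imprinting in Endosperm
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying how transposable elements
    distribute transcription factor binding motifs and how this shapes
    genomic imprinting in the seed endosperm. Provides replicate-supported
    ChIP peak intersection and nearest-TSS target annotation, CArG-box
    motif scanning with perfect and nearly-perfect classification and
    density statistics, a Monte Carlo permutation test of binding-site
    overlap with transposon superfamilies using a size-matched promoter
    shuffle, local-alignment homology clustering of motif-carrying
    transposon copies, allele-specific chromatin signal binning with
    metagene summaries and k-means profile clustering, a ploidy-aware
    maternal and paternal expression-ratio classifier of imprinted genes,
    and a synthetic-data generator with machine-readable planted truth
    so that every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
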