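Package: refeedr
Title: Kinetic Analysis of Fasting-Refeeding Transcriptional and Enhancer Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis framework for temporally organized liver responses to
    fasting and refeeding across five feeding states (ad libitum, fasted, and
    three refeeding time points). Implements negative-binomial pairwise
    differential testing with Benjamini-Hochberg correction, kinetic pattern
    classification of genes and enhancers (recovered, overshoot, early and late
    refeeding induction), k-means clustering with a one-minus-Pearson metric,
    lipid-pathway gene-group filtering and fold-change comparison,
    peak-to-nearest-gene linkage with proximal-enhancer fractions, signal-track
    quantification conventions, and bivariate genomic footprinting (footprint
    depth by flanking accessibility with Tukey-depth bagplot outliers). Includes
    a synthetic-data generator with planted ground truth emulating the
    five-condition study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
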