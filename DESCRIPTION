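Package: DielShift
Title: Diel Light-Shift Transcriptome, Cytometry and qPCR Analysis Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for diel light-shift and UV-stress experiments
    in picophytoplankton. Implements 3'-biased tag RNA-seq quantification
    over 403-nt terminal-exon windows with housekeeping-gene normalization,
    a dual-baseline differential-expression framework with signed fold
    changes and fold-category bins, coverage-driven chloroplast gene-model
    refinement (CDS extension and novel ORF discovery), bead-normalized
    flow-cytometry summaries, growth-rate and irradiance-response analysis,
    and 2^-ddCt relative quantification for qPCR. Ships a synthetic-data
    generator that emulates the statistical structure of such experiments
    (high-copy chloroplast compartment, strong 3' read bias, overdispersed
    replicate counts, diel drift plus treatment effects) with full ground
    truth, so every stage is testable without external data.
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
    Biostrings,
    rtracklayer,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Annotation, FlowCytometry, qPCR
RoxygenNote: 7.3.3
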