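Package: methylink
Title: Reduced-Representation Bisulfite Methylome Analysis and
    Methylation-Expression Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing reduced representation bisulfite
    sequencing (RRBS) methylomes in TE-rich plant genomes and for linking
    differential methylation to differential gene expression. Implements
    in-silico MspI digestion and size selection of a reference genome,
    cytosine context assignment (CG/CHG/CHH), replicate pooling,
    genome-scale methylation summaries, kernel-smoothed two-proportion
    score tests for differentially methylated region (DMR) calling with
    strict and relaxed presets, DMR annotation against genes, promoters
    and transposable elements, nearest-gene assignment, exact Fisher
    contingency tests linking methylation and expression, and a seeded
    synthetic-data generator emulating a small TE-rich genome with planted
    DMRs and differentially expressed genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
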