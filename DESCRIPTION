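Package: splicescreen
Title: Splicing-Reporter Screen and Intron Splicing-Efficiency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing fission-yeast splicing at two scales: a
    plate-based dual-fluorophore (YFP/RFP) splicing-reporter screen read out
    by flow cytometry (hierarchical gating, autofluorescence-corrected median
    ratios, replicate t-tests and hit calling), and genome-wide per-intron
    splicing-efficiency quantification from junction reads with downstream
    analyses (decile comparison, extreme-intron selection, splice-site
    composition matrices, intron length and A/T content, multi-intron
    co-splicing profiles, expression association, and a simplified
    differential-expression surrogate). A synthetic-data generator produces
    genomes, annotations, junction and gene counts, and cytometry plates
    under configurable genotype-specific splicing-defect models with a
    ground-truth table for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
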