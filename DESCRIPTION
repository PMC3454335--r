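Package: ExonScreen
Title: Discovery and Characterization of Exonic Transcriptional Regulatory Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and characterizing transcriptional
    regulatory elements embedded in protein-coding exons and untranslated
    regions. Implements dual-luciferase reporter screen statistics (quantile
    normalization across plates, two-standard-deviation candidate selection,
    replicated one-sample t confirmation under false discovery rate control),
    genomic-context classification of confirmed elements (exon-type location,
    feature-track overlap, CpG-island detection), sliding-window empirical-null
    tests of per-base conservation and GC-content tracks, SNP-based
    population-diversity comparisons with codon-aware consequence
    classification, and factorial ANOVA validation of transcription-factor
    cis-regulation. A synthetic-data generator with known ground truth stands
    in for wet-lab measurements and external genome-browser tracks so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'context.R'
    'stats.R'
    'diversity.R'
    'expression.R'
    'io.R'
    'screen.R'
    'simulate.R'
    'windownull.R'
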