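Package: editatlas
Title: Brain RNA Editing Atlas Analysis with Proteogenomic Validation and
    Two-Stage Disease Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for cohort-scale A-to-I RNA editing analysis:
    quality control and genomic annotation of editing calls derived from
    RNA-seq variant tables, prediction of re-coding proteoforms and their
    tryptic peptides for proteogenomic search databases, iterative
    median-polish (TAMPOR) removal of batch-specific variance from TMT
    peptide abundance matrices anchored on pooled global internal standard
    channels, and a two-stage disease-association framework combining
    per-dataset general linear models with inverse-variance fixed-effects
    meta-analysis, mixed-model regional contrasts, neuropathology and
    cognitive-decline models, and principal components of top events. A
    synthetic-data module generates every input with known ground truth
    (planted regional and diagnosis effects, batch factors) so that all
    stages are testable end to end without access to protected human data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    lme4,
    lmerTest,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
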