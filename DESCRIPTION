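Package: editscreen
Title: Fitness Estimation and Concordance Analysis for Base-Editing and
    Deep Mutational Scanning Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing pooled variant-function screens in
    growth-factor-dependent cell systems. Implements growth-rate
    estimation from mutant allele frequencies and viable-cell counts at
    two timepoints, skew-normal mixture modelling of bimodal fitness
    landscapes with Z-score hit calling, sgRNA counting and
    median-of-ratios fold-change analysis for adenine base editor
    dropout screens, prediction of editing-window base edits and their
    protein consequences, a weighted sgRNA fitness model with a
    multiplicative compound-mutant null, quadrant and odds-ratio
    concordance analysis between guide-level and variant-level
    measurements under a ladder of filters, and error-aware direct edit
    calling from paired amplicon reads. A synthetic-data module
    simulates complete screens with known ground truth for validation
    of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
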