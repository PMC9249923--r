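Package: planstate
Title: Cell-State Dysregulation Mapping for Planarian Stem-Cell Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for mapping transcriptome dysregulation onto
    planarian cell states. Implements negative-binomial exact-test
    differential expression with TMM normalization and conditional-likelihood
    dispersion estimation, derivation of sorted-fraction (X1/X2/Xins and
    PIWI-HI/LO/NEG) signature transcript sets, overlap mapping of dysregulated
    transcripts onto fraction signatures and single-cell lineage subclusters
    with Fisher's exact test over an explicit detection universe,
    flow-cytometry gate calibration and fraction quantification, and Livak
    delta-delta-Ct relative quantification. A synthetic-data generator built
    on an explicit cell-state composition model (neoblast, progeny, mature
    programs; differentiation-delay and irradiation-ablation perturbations)
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
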