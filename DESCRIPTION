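Package: dyemix
Title: Mixed-Model and Mixture-Model Differential Expression for Two-Colour
    Dye-Swap Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-colour dye-swap microarray experiments
    with a small number of hybridisations: spot-level quality filters based on
    signal-to-noise and mean/median agreement, background correction and log2
    transformation, joint normalization and per-gene expression estimation
    through a linear mixed model fitted by REML (EM steps with
    average-information acceleration), per-gene phenotype contrasts built from
    BLUP solutions and their prediction-error variances, differential
    expression calling by a two-component normal mixture with a
    posterior-probability false discovery rate rule, a deterministic
    probe-to-gene annotation rule engine over interval and BLAST-hit tables,
    and delta-delta-Ct relative quantification of qPCR validation data. A
    synthetic-data generator emulating a multi-chip dye-swap design with three
    phenotypes and two sexes makes every stage testable without raw scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
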