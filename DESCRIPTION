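Package: pulsaScreen
Title: Simulation and Scoring of Pulse-Shape FACS CRISPR Knockout Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for pooled CRISPR knockout screens that sort
    cells by flow-cytometry Pulse Shape Analysis (PulSA), a gating strategy
    that separates cells with punctate protein inclusions from cells with
    diffuse reporter signal using the fluorescence pulse height-to-width
    relationship. Provides a synthetic screen generator (Brunello-like guide
    library, planted gene effects on inclusion formation, low-MOI single-guide
    cell populations), a physical model of the cytometer pulse with
    expression and tail gating, amplicon read synthesis and flank-anchored
    sgRNA spacer counting, and the screen scoring algorithm: depth
    normalization, per-guide log fold changes, rank-windowed local Z-scores,
    gene phenotypes from the two strongest guides, permutation p-values with
    non-targeting-control pseudo-gene calibration, and hit calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CRISPR, PooledScreens, Software, FlowCytometry, Sequencing
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'screenModel.R'
    'pulse.R'
    'gating.R'
    'sequencing.R'
    'countsIO.R'
    'scoring.R'
    'pipeline.R'
    'pulsaScreen-package.R'
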