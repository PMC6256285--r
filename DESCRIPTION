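Package: synaptiq
Title: Quantification of Synaptic Puncta, Colocalization and Synaptic Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable quantification stack for synapse biology experiments in
    cultured neurons: 3D segmentation of fluorescent synaptic puncta with
    26-connectivity labeling and seeded watershed separation, object-based
    pairwise colocalization and spine-versus-shaft enrichment, miniature-EPSC
    detection and kinetics, current/voltage rectification-index analysis of
    evoked AMPA-receptor currents, dendritic-spine dF/F transient
    quantification, and the cohort-based statistical layer (equal events per
    cell, Kolmogorov-Smirnov and rank-based test battery). Ships ground-truthed
    synthetic generators for fluorescence stacks, mEPSC traces, I/V sweep
    families and spine time-lapses so the whole pipeline is testable without
    primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite,
    signal,
    minpack.lm,
    EBImage,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
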