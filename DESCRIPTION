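Package: fretscreen
Title: Analysis of FRET-Based High-Throughput Screens for Protein-DNA
    Interaction Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis pipeline for FRET-based high-throughput
    screening of small-molecule inhibitors of protein-ssDNA interactions,
    modeled on a RAD52 inhibitor discovery campaign. Provides plate-level
    quality control (Z'-factor, signal-to-noise, signal-to-background), hit
    calling against control wells, cherry-pick rescreen confirmation and
    optical-artifact flagging; calibrated two-channel FRET computation with
    compound-artifact correction and four-parameter inhibition-model (IC50,
    Hill slope, saturation FRET) fitting; biexponential annealing-kinetics
    fitting with extent-versus-concentration IC50 estimation; ROC/AUC
    validation of virtual-screening score lists against decoys; and seeded
    synthetic-data generators emulating every assay input for benchmarking
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
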