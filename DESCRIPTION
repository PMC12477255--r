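Package: cytopipe
Title: Simulation and Analysis Pipeline for Barcoded Mass Cytometry Immune Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end tools for analysing multiplexed mass cytometry (CyTOF)
    immune-profiling experiments of the kind used in non-human primate vaccine
    challenge studies: bead-standard sensitivity normalization, k-of-n palladium
    barcode debarcoding with separation and Mahalanobis purity filtering,
    config-driven hierarchical gating of mononuclear immune populations,
    extraction of population frequencies, CBC-anchored pseudo-absolute counts
    and arcsinh-median phospho-signaling stimulation responses, and a
    statistical layer (group t-tests and ANOVA with Benjamini-Hochberg
    correction, volcano classification, combined-rank feature selection,
    group Z-scores, log2 ratios versus control, and clinical-outcome Pearson
    correlations). A fully specified synthetic-data generator emulates barcoded
    acquisitions with ground-truth labels so every stage is testable without
    instrument data, and a compact FCS 3.1 reader/writer handles event files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
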