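Package: ensembleseq
Title: Phase-Locked Ensemble Sequence Analysis for Behavioral Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-unit recordings made during
    naturalistic predatory hunting. Classifies units as excited or
    inhibited per behavioral phase against a resampled-baseline null,
    types units by PCA and complete-linkage hierarchical clustering of
    phase z-scores, detects phase-locked population sequences with a
    shuffle-controlled ridge-to-background statistic, identifies
    optogenetically tagged units (latency rank test, waveform
    similarity, reliability), computes spike-triggered EMG curves with a
    surrogate significance band, derives hunting-efficiency behavior
    metrics from an ethogram, and screens units with standard
    spike-sorting quality metrics. Includes a synthetic session
    generator so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
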