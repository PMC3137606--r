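Package: fetaluco
Title: Simulation and Analysis of Fetal Electrocortical and Cardiovascular
    Responses to Repetitive Umbilical Cord Occlusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying fetal electrocortical (ECOG) and cardiovascular
    adaptation to labour-like repetitive umbilical cord occlusions (UCO) in the
    near-term ovine fetus.  Provides a synthetic cohort generator that emulates
    the three-phase (mild/moderate/severe) UCO protocol with chemoreflex heart
    rate decelerations, biphasic arterial pressure responses, electrocortical
    state alternation and progressive acidemia; signal operators for zero-phase
    ECOG band-pass filtering, 4-second amplitude and 95% spectral edge
    frequency (SEF) series, and heart-rate extraction from arterial-pressure
    systolic peaks; event-locked per-occlusion feature extraction and
    per-series aggregation; detectors for the late SEF "spiking" pattern
    ("adaptive brain shutdown") and the hypotensive pressure response, with
    lead times to severe acidemia (arterial pH below 7.00); and nonparametric
    repeated-measures statistics and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
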