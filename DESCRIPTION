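Package: ripplephase
Title: Oscillation Detection and Spike-Phase Coupling Analysis for
    Hippocampal Field-Potential Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing interneuron discharges during hippocampal
    network oscillations: zero-phase band-pass decomposition and envelope
    extraction of local field potentials, dual-threshold detection of
    transient high-frequency events (sharp-wave ripples), circular
    statistics for spike-phase coupling (resultant vector, Rayleigh and
    Watson-Williams tests), randomization tests of event-related firing-rate
    modulation, intra-event core-frequency estimation by zero-crossing,
    peak-interval and complex Morlet wavelet methods, and a synthetic
    LFP/spike-train generator with known ground truth that makes every
    analysis stage verifiable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
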