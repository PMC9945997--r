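Package: ripplepipe
Title: Detection and Statistics of Cortical Ripple Events in Laminar Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting high-frequency ripple events in laminar
    local field potential (LFP) recordings and for the statistics that relate
    them to behaviour. Provides bipolar rereferencing, a dual-threshold
    band-power ripple detector with spectral validation, current source
    density and layer assignment for laminar probes, epoch- and
    condition-resolved ripple rates with repeated-measures factorial tests,
    shuffle-predictor-corrected cross-area correlograms, ripple-triggered
    power-power comodulograms, ripple-locked spike rates with matched-control
    resampling, mixed-effects models of reaction times, and a synthetic
    session generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
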