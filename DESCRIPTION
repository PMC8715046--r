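Package: pupilphase
Title: Event-Locked Pupillometry with Onset-Latency Estimation and
    Phase-Windowed Within-Subject ANOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-locked pupillometry experiments in
    which pupil dilation is decomposed into a fast (transient) and a sustained
    component, as in pharmacological studies that dissociate iris sphincter
    and dilator contributions.  Provides pupil area-to-diameter conversion,
    nan-aware moving-average smoothing, velocity-based blink detection and
    masking, cue-locked epoch extraction with pre-stimulus baseline
    correction, dilation onset-latency estimation by the 25/75%-of-peak
    extrapolation method, phase-windowed response summaries, a balanced
    within-subject factorial ANOVA with pooled-error simple main effects,
    Ryan's sequentially rejective post-hoc procedure, and a synthetic
    pupil-trace generator that emulates the full experimental design (drug
    presets, blinks, hippus, sensor noise, reaction times) so that every
    stage of the pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
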