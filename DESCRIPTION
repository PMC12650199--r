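Package: sleepcoupler
Title: Sleep Staging, Oscillatory Event Detection, and Hippocampal-Cortical
    Coupling Analysis for Rodent Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rodent sleep electrophysiology: EEG/EMG
    sleep staging into wake, NREM and REM epochs with stage-relative power
    spectra and sleep-architecture summaries; detection of hippocampal
    sharp-wave ripples and prefrontal delta waves and sleep spindles by
    band-filtered, z-scored envelope thresholding with duration criteria;
    quantification of delta-spindle, ripple-delta and ripple-delta-spindle
    coupled sequences during sleep and their change from a pre-encoding to
    a post-encoding recording session; the object-location discrimination
    index and zero-maze zone summaries; a synthetic session generator that
    embeds ground-truth state sequences and coupled oscillatory events so
    that every stage of the pipeline can be validated without animal data;
    and minimal EDF signal input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
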