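Package: localsleep
Title: Local Cortical Slow Waves, OFF Periods and Arousal State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for optogenetic thalamic reticular nucleus
    (TRN) stimulation experiments: multitaper spectral estimation and
    band-power effect statistics on LFP/EEG, automatic slow-wave event
    detection, population OFF-period detection with a gamma-renewal null,
    delta-phase locking statistics (phase-locking value, Kullback-Leibler
    modulation index), point-process spike-history GLMs, rule-based rodent
    sleep scoring from EEG/EMG, Horn-Schunck optical-flow motion scoring,
    and an optical-fiber irradiance model for stimulation depth. Includes
    a synthetic-session generator with ground-truth labels so every stage
    is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
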