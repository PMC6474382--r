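Package: sdrtes
Title: Closed-Loop Short-Duration Repetitive tES Protocol Simulation and
    Sleep EEG Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of closed-loop short-duration
    repetitive transcranial electrical stimulation (SDR-tES) during nap
    sleep. Provides a synthetic sleep-EEG generator (stage-structured
    hypnograms, slow oscillations with frontal-dominant topography,
    up-state-coupled spindles, 1/f background, stimulation artifacts and a
    stimulation-efficacy model), offline and causal slow-oscillation
    detection with a dynamic 3-sigma threshold, the stimulation scheduler
    and waveform, Welch spectral density and multitaper coherence,
    phase-locked spindle energy, pre-stimulation predictors of stimulation
    efficacy, hypnogram summarisation with stimulation-epoch relabeling,
    and the accompanying statistics toolbox (paired tests, BH-FDR channel
    topography, Greenhouse-Geisser repeated-measures ANOVA, exact
    noncentral-t power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
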