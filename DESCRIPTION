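Package: emfeeg
Title: Bayesian Analysis of Radiofrequency Exposure Effects on Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sham-controlled crossover studies of radiofrequency
    electromagnetic field (EMF) exposure effects on the resting
    electroencephalogram. Provides a synthetic multichannel EEG generator
    with 1/f background, region-weighted alpha activity, mains harmonics and
    a GSM 217 Hz pulsation artifact; a Welch spectral pipeline producing
    per-region alpha-band power and per-subject session contrasts; marginal
    likelihood (Bayes factor) comparison of five normal-mean models over a
    3 x 3 grid of diffuse priors with deterministic quadrature and
    importance-sampling cross-checks; posterior summaries for the
    two-group model; a random-intercept mixed-model companion test; and
    phantom-recording quality control for pulsed-carrier interference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
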