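Package: popgate
Title: Analysis of All-or-None Population Cortical Responses from
    Widefield Imaging and Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterizing stochastic all-or-none
    ("population ON/OFF") sensory-evoked cortical responses from widefield
    flavoprotein autofluorescence and calcium imaging, cellular calcium
    imaging, local field potentials, and whole-cell recordings. Implements
    delta-f/f computation with pre-stimulus baselines and annular neuropil
    correction, a z-score plus waveform-shape trial classifier, percent-ON
    summaries with logistic gating fits, peak-latency variance as a
    population synchrony metric, postsynaptic-current charge (AUC)
    measurement with OFF/ON normalization, membrane-potential bimodality
    analysis via Gaussian mixtures, the study's statistical layer
    (normality gating, paired tests, repeated-measures ANOVA with
    Bonferroni post hocs, Kruskal-Wallis with Dunn post hocs, log-linear
    fits), and a phenomenological synthetic-data generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    mclust,
    nortest,
    pracma,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
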