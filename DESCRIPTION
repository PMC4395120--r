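Package: archepsy
Title: Simulation and Classification of Autonomic Responses to Affective Film Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how well autonomic nervous system signals and
    introspective Self-Assessment Manikin (SAM) ratings discriminate elicited
    psychological states. Provides a seeded generator of synthetic multi-channel
    physiological cohorts (ECG, skin conductance, respiration, skin temperature)
    with class-dependent autonomic modulation; signal processing into heart
    rate, heart-rate-variability summaries, tonic/phasic electrodermal
    components, respiration rate and temperature series; assembly of a
    canonical 158-feature vector per stimulus epoch with baseline-referenced
    min-max normalization; PCA-based dimension reduction with kNN, naive Bayes
    and regularized LDA classifiers under leave-one-out cross-validation; and
    an exhaustive three-subject-subset resampling procedure with paired t-tests
    comparing classification accuracy against chance and between data
    modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
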