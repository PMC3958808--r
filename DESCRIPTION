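Package: elasticfit
Title: Elastic Cloud Resource Allocation and Expert Fitness Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation toolkit for a Poisson-threshold elastic cloud
    autoscaler driven by an exponential moving average of per-interval
    request counts, together with an expert fitness-diagnosis pipeline
    for three-level (strong/moderate/weak) classification of elder
    physiological test results. Provides synthetic request-pattern
    generators (linear, logarithmic, repetitive, combined), a
    discrete-time allocation simulator with MAPE and quality-of-service
    summaries, Gaussian naive Bayes, k-nearest-neighbour and linear
    discriminant classifiers evaluated by stratified k-fold
    cross-validation with per-class precision/recall/F1, a synthetic
    elder-cohort generator with a tunable class-separation knob, JSON
    prediction messaging, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
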