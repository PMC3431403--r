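Package: fcLifespan
Title: Lifespan Trajectories and Brain-Age Prediction from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterises lifespan development of whole-brain resting-state
    functional connectivity and predicts individual brain age from it. The
    package builds Fisher-z connectivity features from regional BOLD time
    series (band-pass filtering, detrending, nuisance regression, Pearson
    correlation, upper-triangle vectorisation, framewise-displacement motion
    summaries), fits per-connection linear and quadratic age trajectories
    with sex and centre covariates (AICc model selection, leave-one-out
    robust significance screening, peak-age extraction), learns a supervised
    Locality Preserving Projections manifold of the connectivity space with
    a PCA baseline, and regresses manifold coordinates on age with global
    and locally adjusted support vector regression evaluated by
    subject-level leave-one-out cross-validation. A synthetic-cohort
    generator with planted developmental trajectories makes every stage
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
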