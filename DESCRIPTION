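Package: surveybbn
Title: Discrete Bayesian Belief Networks for Patient-Experience Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for modelling interdependencies among
    sections of trust-level patient-experience surveys with discrete Bayesian
    belief networks. Provides a synthetic survey generator calibrated by
    section-level moments, correlations and per-section Cronbach alphas;
    mean imputation and reliability/descriptive reporting; equal-width,
    equal-frequency and k-means discretization with silhouette-based state
    selection; three structure learners (score-based hill climbing, the PC
    constraint-based algorithm and Greedy Thick Thinning) with BDeu scoring;
    exact inference by variable elimination; stratified k-fold predictive
    validation with confusion matrices and ROC; and probabilistic sensitivity
    analysis via state-doubling interventions producing net-effect tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    cluster,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
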