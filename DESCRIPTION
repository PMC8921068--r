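Package: hmgm
Title: Hidden Markov Graph Models for Multi-Subject Brain-State Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits multi-subject Gaussian-observation hidden Markov models to
    regional brain-activity time series and converts the fitted states into a
    multiplex graph model. The number of states is selected by
    leave-one-subject-out cross-validated maximum entropy of fractional
    occupancy. Each state becomes a layer: a Markov information graph whose
    directed edge weights are row-normalised absolute correlations derived
    from the state covariance, with layers linked by the state transition
    matrix. Temporal and spatial communities are detected with Louvain
    optimisation scored by directed (Leicht-Newman) modularity, hub states are
    chosen by a within-community centrality z-score, and spatial communities
    are ranked by a random-walk null-model T-score built on the functional
    homogeneity quadratic form. Includes a fully synthetic ground-truthed data
    generator, Horn's parallel analysis for dimension selection, permutation
    significance testing for modularity, Ward clustering of occupancy
    profiles, and one-step-ahead projection of per-state term scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, igraph, ape, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), mclust, optparse, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
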