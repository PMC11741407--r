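Package: habitiron
Title: Habitual Decision-Making Indices and Striatal Tissue-Iron Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit linking habit-like perseveration in the
    two-stage sequential decision-making task to developmental trajectories of striatal
    tissue iron measured by normalized T2*-weighted (nT2*w) imaging. Provides a generative
    model of the task (drifting reward probabilities, 70/30 transitions), hybrid
    model-based/model-free reinforcement-learning agents with a perseveration bonus and
    their exact likelihoods, hierarchical logistic stay-probability models yielding
    model-based, model-free and first-stage-stay indices, maximum-a-posteriori fitting of
    the agent family with parameter-recovery harnesses, nT2*w preprocessing rules
    (coverage-map z-normalization, motion censoring, voxelwise median, region-of-interest
    extraction, batch harmonization), penalized-spline mixed models with
    varying-coefficient terms and simulation-based windows of significance, and an
    accelerated-longitudinal synthetic cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    lme4,
    MASS,
    mgcv,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
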