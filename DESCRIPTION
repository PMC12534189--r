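Package: formucomet
Title: Transformer-Based Efficacy Scoring and Screening of Multi-Component
    Nanoparticle Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the transfection efficacy of lipid
    nanoparticle (LNP) and polymer-lipid formulations from their full
    composition: component molecular structures, molar percentages and
    synthesis parameters (N/P ratio, aqueous/organic phase ratio).
    Implements a set-transformer scoring network with per-task CLS tokens
    trained by a pairwise ranking objective with label margin, molar-noise
    augmentation and conflict-averse multitask gradient combination;
    ensemble score normalization and relative-uncertainty filtering for
    virtual-library screening; design-grid enumeration of formulation
    libraries; integrated-gradients feature attribution; k-NN and random
    forest baselines; and a synthetic formulation generator with a known
    ground-truth oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ChemmineOB,
    stats,
    tools,
    utils,
    jsonlite,
    randomForest,
    caret
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
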