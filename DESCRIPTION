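Package: olstscreen
Title: Screening High Autistic Trait from One-Legged Standing Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Posturographic screening of high autistic trait in young
    children from one-legged standing tests (OLST). Computes center-of-
    pressure (COP) trajectories from pressure-mat recordings, joint-angle
    series from 2-D skeletal keypoints, and a 16-variable feature table
    (COP sway, overall balance, and COP-joint coupling correlations);
    classifies high versus low autistic trait with a linear support vector
    machine under simultaneous feature-subset and cost selection evaluated
    by leave-one-out cross-validation; calibrates class probabilities with
    Platt scaling; and interprets fitted models through exact linear SHAP
    attributions and probability-SRS rank correlations. A synthetic-cohort
    generator with severity-dependent sway dynamics makes every stage of
    the pipeline testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
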