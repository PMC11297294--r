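Package: clingaze
Title: Eye-Tracking Analysis of Physician Attention During AI-Supported
    Prescribing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile eye-tracking experiments on
    clinician interaction with AI decision support. Detects fixations
    (dispersion-threshold, I-DT) and blinks (pupil-confidence dips) from
    raw gaze streams, attributes gaze to hierarchical regions of interest
    with moving bounding boxes, computes per-trial attention metrics with
    a chance-gaze ("visual real-estate") correction, derives
    advice-taking behaviour metrics (influence of AI, practice variation,
    advice distance), and runs the safe-versus-unsafe statistical
    comparisons (Student's t, Pearson correlation, post-hoc power). A
    seeded synthetic-experiment generator emulates the six-scenario
    simulation-suite design with known ground truth so every stage is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
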