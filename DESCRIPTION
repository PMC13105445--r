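Package: coprqa
Title: Center-of-Pressure Posturography and Recurrence Quantification for
    Human-Robot Collaborative Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for force-plate posturography during cyclic
    manipulation tasks performed with and without robotic assistance. Computes
    per-plate and total center-of-pressure (COP) trajectories from raw
    six-component force-platform channels, segments task repetitions from a
    wrist marker trajectory, extracts manipulation phases, and derives linear
    sway statistics (mean distance, mean velocity, 95% confidence-ellipse
    area, sway area) per movement cycle together with recurrence
    quantification analysis (recurrence rate, determinism, and their ratio)
    of the radial, anteroposterior, and mediolateral COP components using
    cycle-length time-delay embedding. Includes within-subject nonparametric
    statistics (Shapiro-Wilk gate, Friedman omnibus, pairwise Wilcoxon with
    effect sizes) and a seeded synthetic-cohort generator with ground-truth
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
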