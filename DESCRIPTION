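Package: bayescat
Title: Signal Detection and Ideal-Observer Analysis of Orientation
    Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing perceptual decision-making in orientation
    categorization tasks with manipulated category base rates (priors) and
    stimulus contrast (sensory uncertainty). Implements standard
    signal-detection estimation of sensitivity (d') and decision criterion
    (c), ideal-observer benchmarks (optimal likelihood-ratio criterion and
    optimal category boundaries), suboptimality metrics (criterion error,
    boundary error), a two-step estimator of sensory noise and decision
    boundaries for embedded (same-mean, different-variance) category tasks,
    a trial-level synthetic-cohort generator with tunable observer
    suboptimality for parameter-recovery validation, and an end-to-end
    analysis pipeline with psychometric binning, outlier-exclusion rules
    and group summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
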