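Package: myoracle
Title: Automatic Detection of Instability in Prosthetic Hand Myocontrol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an automatic "oracle" that
    detects failures (instability events) in simultaneous-and-proportional
    sEMG myocontrol of a multi-fingered prosthetic hand. Provides a session
    data model for synchronized myocontrol prediction and digit-status
    traces, a synthetic session simulator with known ground truth
    (grasp-carry-release tasks, threshold-triggered hand actuation,
    injected oscillatory instability events, unreliable button reporting),
    sliding-window count features (threshold crossings and digit status
    changes), a class-weighted support vector machine detector evaluated
    under nested cross-validation with balanced-error-rate and ROC/AUC
    metrics, and an analysis layer covering per-zone failure summaries,
    least-squares trend diagnostics with Cook's distances, group
    comparisons, factorial ANOVA with Tukey follow-up, and noncentral-F
    statistical power and sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
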