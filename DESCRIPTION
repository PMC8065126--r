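Package: oscidyn
Title: Rhythmic and Aperiodic Neural Dynamics, Decision Modeling, and
    Multivariate Statistics for Task-Uncertainty Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how task uncertainty modulates cortical
    excitability in multichannel electrophysiology. Implements time-resolved
    sample entropy over discontinuous trial segments, aperiodic (1/f)
    spectral-slope estimation with oscillatory-peak exclusion, single-trial
    rhythmic-episode detection with background-referenced power thresholds,
    alpha-phase to gamma-amplitude coupling with surrogate-normalized
    modulation indices, steady-state visual-evoked potential estimation,
    two-boundary drift-diffusion simulation and maximum-likelihood fitting,
    pupil-derivative phasic-arousal metrics, and the group statistics that
    link them: first-level load effects, partial repeated-measures
    correlation, cluster-based permutation tests, and task/behavioral
    partial least squares with permutation and bootstrap-ratio inference.
    A synthetic-study generator with known ground truth makes every stage
    testable end to end.
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
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
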