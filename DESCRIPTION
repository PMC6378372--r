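Package: fingercue
Title: Cue-Summation Analysis of Force-Biased Fingertip Distance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing haptic matching experiments in which tactile
    and non-tactile (efference copy plus proprioception) force-related inputs
    bias the estimation of fingertip relative position. Provides a seeded
    generator of trial-level data emulating three matching experiments,
    sense-phase compliance checks, per-trial matching-error computation with
    per-subject null-condition baseline correction, a nonparametric test
    kernel (exact and approximate Wilcoxon signed-rank, Kruskal-Wallis with
    Dunn post-hoc contrasts, Cohen's r effect sizes), a linear cue-summation
    analysis with tactile/non-tactile contribution weights and
    inverse-variance reliability classification, a quartile-exceedance
    strength-of-bias statistic, and a reproducible end-to-end pipeline with
    machine-readable outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
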