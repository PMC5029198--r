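Package: cohermetrics
Title: Coherence-Threshold Psychophysics: Stimuli, Adaptive Staircases and
    Reading-Skill Regressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for coherence-based visual
    psychophysics of global motion and global form perception. Generates
    random-dot kinematograms, spatially one-dimensional bar stimuli, static
    global-form images and temporally-defined global-form sequences as
    geometric frame sequences; simulates observers through Weibull
    psychometric functions or stimulus-driven decision rules; implements the
    transformed 3-down/1-up adaptive staircase with step halving at
    reversals and mean-of-reversals threshold estimation; builds calibrated
    synthetic participant cohorts with correlated reading measures; and
    provides the downstream statistics: a correlation-matrix PCA reading
    composite, two-step hierarchical regressions with R-squared-change F
    tests and local Cohen's f-squared, pooled two-sample t tests from
    summary statistics, and cross-task threshold correlations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
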