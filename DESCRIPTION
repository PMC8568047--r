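Package: habitrace
Title: Visual Escape Behavior and Neuronal Habituation to Looming Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for larval-zebrafish visual habituation
    experiments that decompose looming stimuli into their luminance (dim) and
    motion (checkerboard) components. Defines loom/checkerboard/dim stimulus
    trains and calcium-kernel regressors, classifies stimulus-responsive
    regions of interest (ROIs) from 2 Hz fluorescence traces by regression
    against a stimulus regressor with a median + 2 SD r-squared threshold,
    quantifies per-ROI habituation by robust least-absolute-residual fitting
    of an exponential decay f(x) = a + b*exp(-c*x) to per-presentation
    response maxima, clusters response profiles with validation and merging
    rules, and analyses behavioral escape probability with rank-based
    repeated-measures statistics (ANOVA-type statistic, Mann-Whitney U,
    Friedman). Includes a seeded synthetic-cohort generator emulating
    CaImAn-style extracted traces and ViewPoint-style tracking output with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
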