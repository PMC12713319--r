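Package: pupilcb
Title: Pupillometry Analysis of Covert Detection in Choice Blindness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-related pupillometry in choice
    blindness experiments, where participants who fail to report a manipulated
    choice outcome may nevertheless detect it covertly. Provides synthetic
    cohort generation (trial schedules, reporting phenotypes, pupil traces
    with blinks, saccades, drift and event-related dilation), the standard
    preprocessing chain (blink interpolation, 0.02-4 Hz zero-phase Butterworth
    filtering, z-scoring, downsampling to 100 Hz, canonical pupil impulse
    response nuisance regression, epoching and quality control), behavioral
    report tabulation with signal-detection scoring and Cohen's kappa,
    pointwise paired t-tests with false-discovery-rate control, window
    statistics, mixed-effects models of reporting and pupil size with
    intraclass correlation, a leave-one-subject-out midpoint-threshold pupil
    classifier with exact binomial testing, and simulation-based power
    analysis for paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
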