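Package: pupilmath
Title: Pupillometry of Mental Arithmetic and Math Anxiety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for task-evoked pupillometry
    of mental arithmetic in relation to math anxiety. Generates the
    auditory multiplication task (24 problems, 72-trial sessions) and a
    synthetic cohort with Gaussian-copula-correlated questionnaire scores,
    trial accuracy and 500 Hz pupil traces with blinks; implements the
    full preprocessing chain (velocity-based artifact detection with gap
    extension, missingness-based trial rejection, linear interpolation,
    cubic-spline smoothing, 25 ms median binning, participant-wise
    z-transform, baseline realignment and outlier-baseline rejection) and
    feature extraction (tonic baseline, maximum dilation, peak latency);
    provides crossvalidated mixed-effects timepoint selection with
    consensus clusters, best-subset regression with BIC-approximate Bayes
    factors, leave-one-subject-out crossvalidation, power curves, and
    psychometric descriptives (Pearson correlations with Fisher-z
    intervals, Cronbach's alpha, k-means clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
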