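Package: drivecb
Title: Change-Blindness and Gaze Analysis for Simulated Driving Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coding and analysing change-detection experiments embedded
    in simulated driving: dispersion-threshold (I-DT) fixation extraction from
    head-referenced gaze streams, dwell analysis on dynamic three-dimensional
    areas of interest, reaction-time validated response coding with a
    mean-plus-three-standard-deviations cutoff, looked-but-failed-to-see (LBFTS)
    classification, event-aligned gaze time-courses, driving telemetry metrics,
    temporal-proximity and learning-effect analyses, and an inferential layer
    (ANOVA with partial eta squared, paired t with Cohen's d, Tukey and
    Bonferroni post hocs). A synthetic-data generator emulates multimodal
    session logs (gaze at 120 Hz, telemetry, button presses, change-event
    schedules) so every pipeline stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
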