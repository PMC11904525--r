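Package: pdrkit
Title: Detection of Pupil Dilation Responses to Pure-Tone Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pipeline for detecting task-evoked pupil dilation responses
    (PDRs) in eye-tracker pupil-diameter recordings from auditory
    stimulation protocols. Provides reading and validation of per-eye
    pupil sample tables and stimulus event tables, confidence-based
    artifact masking with linear interpolation, resampling to a regular
    50 Hz grid, linear detrending, segmentation into 3-s pre-stimulus
    normalized epochs with interpolation-based quality control, a
    signed-area statistic compared between stimulated and unstimulated
    recordings by a pooled-variance t-test, block-wise adaptation
    analysis, regression of evoked amplitude on pre-stimulus pupil size
    with slope-equality and correlation comparisons, and a synthetic
    pupil-session generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
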