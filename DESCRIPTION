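Package: pupiltime
Title: Temporal Analysis of Pupil Dilation and Gaze Behavior from High-Speed Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for event-related pupillometry and gaze analysis of
    two-group emotion-viewing experiments recorded at 300 Hz. Implements
    artifact-aware pupil preprocessing (size and dilation-speed filters, blink
    margins, two-pass trend-line outlier removal, binocular combination,
    gap interpolation, smoothing, baseline correction), velocity-based fixation
    detection with an adaptive data-driven threshold, area-of-interest gaze
    outcomes including 50 ms looking-time progression, varimax-rotated PCA
    temporal pupil components with derived serial time windows, and the linear
    mixed-effects / growth-curve / association models that operate on these
    measures. Ships a ground-truth-labelled synthetic data generator emulating
    a two-group design so every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
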