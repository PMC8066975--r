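Package: handscore
Title: Scoring and Psychometric Evaluation of Multi-Touch Hand Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores raw multi-touch event streams (timestamped pointer
    down/move/up records from a tablet screen) into the outcome measures of a
    six-exercise hand-function assessment for stroke survivors: finger tapping,
    isolated-finger tapping with weight-bearing digits, finger-thumb pincer
    distances, hand opening/closing area, trace-template dissimilarity for
    figure drawing, and timed acquisition of a 4 x 8 target grid. Provides the
    psychometric battery used to validate such instruments, including Pearson
    convergent validity with strength bands, two-way random-effects
    absolute-agreement intraclass correlation ICC(2,1), standard error of
    measurement, minimal detectable change at 95% confidence, z-score outlier
    screening, and severity-stratified group comparison. A synthetic
    touch-stream simulator generates event streams and cohort outcome tables
    with controllable group means, variance components, and outcome-clinical
    correlations so that every scorer and statistic can be exercised without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
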