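Package: circaphase
Title: Circadian Phase Prediction for Shift Workers from Wrist Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the human circadian pacemaker as a forced limit-cycle
    (Van der Pol type) oscillator driven by ambulatory light exposure and,
    optionally, a square-wave non-photic rest/activity signal, and predicts
    the clock time of the core body temperature minimum (CBTmin) as a proxy
    for the urinary 6-sulphatoxymelatonin (aMT6s) acrophase.  Includes
    minute-epoch actigraphy ingestion and rest-interval scoring, mid-sleep
    and oracle phase initialization, cosinor estimation of the measured
    aMT6s reference phase from urine collection blocks, prediction-error and
    phase-shift evaluation statistics, and a synthetic shift-worker cohort
    generator so the full pipeline can be exercised end to end without
    protected field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
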