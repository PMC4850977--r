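Package: skiturns
Title: IMU Sensor Placement and Turn Performance Analysis for Alpine Skiing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for selecting a body location for a wearable
    inertial measurement unit (IMU) on an alpine skier and for quantifying turn
    performance from the selected sensor. Raw multi-location roll-angle traces
    and insole plantar-pressure streams are smoothed, standard-score normalized
    and compared to the foot-pressure weight-shift pattern by Pearson
    correlation; candidate locations are clustered by correlation distance with
    centroid linkage and screened by a zero-crossing turn-detection measure.
    Turn-level performance metrics (turn duration, maximum outer-foot pressure
    ratio) feed lateral-asymmetry two-sample t-tests with data-driven
    pooled/Welch branching and an adaptation-effect correlation analysis across
    attempts. A seeded synthetic-session generator with known ground truth
    supports end-to-end testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
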