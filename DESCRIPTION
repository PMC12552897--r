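Package: drisleep
Title: Nightly Sleep Metrics, Bed-Occupancy Phenotypes and a Sleep-Disturbance
    Index from Contactless Under-Mattress Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for minute-level bed-occupancy streams recorded
    by under-mattress pressure sensors in longitudinal dementia monitoring.
    Localizes and grids sparse minute observations, detects bed-occupancy
    periods and nocturnal episodes, computes nightly sleep metrics (in-bed
    time, bed exits, sleep-state composition, heart and respiration rate),
    applies extreme-value quality filters, compares groups with the Hellinger
    distance and circular statistics, discovers night-level bed-occupancy
    phenotypes by hierarchical clustering, trains an interpretable additive
    boosted state classifier with leave-one-group-out validation, builds
    90-day pre-assessment sleep profiles, derives an ensemble nightly
    sleep-disturbance index with multi-level splitting, and relates the index
    to clinical scale scores with mixed-effects models. Includes a synthetic
    cohort generator emulating the record structure of such sensors so the
    full pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    xgboost,
    lme4,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
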