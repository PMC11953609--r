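Package: tacwear
Title: Minute-Level Transdermal Alcohol Sensor Analysis with Contingency-Management Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and evaluation pipeline for wrist-worn transdermal
    alcohol sensor (TAS) data sampled at one-minute resolution. Classifies
    every minute of a participation window as worn, removed (skin temperature
    below 30 degrees C for more than two minutes), missing because the
    device's 72-hour rolling storage overwrote unsynced data, or missing for
    unknown reasons; detects drinking events as threshold-duration excursions
    in transdermal alcohol concentration (TAC) and aggregates them to
    calendar-day drinking classifications; computes a contingency-management
    (CM) voucher ledger with daily awards, inter-meeting block bonuses and a
    full-period bonus, together with a per-day audit trail; and compares
    sensor day classifications against timeline-followback (TLFB) self-report
    via confusion matrices, diagnostic statistics, and Spearman correlations
    with bias-corrected and accelerated (BCa) bootstrap intervals. A
    synthetic-data generator emulates the sensor and self-report data,
    including device-storage overwriting, removals, ambient-alcohol
    artifacts and imperfect self-report, so the whole pipeline runs with no
    external data and with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
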