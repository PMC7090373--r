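Package: ocor
Title: Total Haemoglobin Mass from Optimized Carbon Monoxide Rebreathing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the optimized carbon-monoxide rebreathing (oCOR)
    analysis pipeline for measuring total haemoglobin mass (tHb-mass) in
    clinical populations: CO dose planning from subject covariates,
    tHb-mass computation from timed carboxyhaemoglobin (COHb%) samples
    with time-dependent corrections for CO lost to exhalation and
    myoglobin, blood/plasma/red-cell volume derivatives, validity gating
    on the COHb rise, and a multi-timepoint stability analysis comparing
    the canonical "7-min" measurement against later sampling times.
    Includes a seeded synthetic wash-in generator with per-subject ground
    truth for parameter-recovery and calibration studies, plus a packaged
    study fixture of published per-patient values for end-to-end
    reproduction of the printed cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
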