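Package: budfreeze
Title: Bud Cold Hardiness Dynamics, Freeze Damage, and Budbreak Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates dormant-season grapevine bud cold hardiness per
    cultivar and population percentile from daily minimum and maximum
    temperatures, accumulates Dynamic Model chill portions from
    latitude-aware hourly temperature interpolation, predicts budbreak as
    the day the projected 50th-percentile hardiness crosses a cultivar- and
    observation-convention-specific threshold, detects freeze-damage events,
    adjusts the surviving population's hardiness percentiles, and derives
    freeze-damage-corrected budbreak, safety margins, freeze-risk day
    counts, and climate-sensitivity diagnostics. Includes a seeded synthetic
    weather and phenology generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
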