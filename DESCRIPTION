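Package: swiftascent
Title: Year-Round Twilight-Ascent Analysis from Multi-Sensor Geolocator Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and model twilight ascents of aerial birds from
    multi-sensor geolocator tags recording light, vertical-axis acceleration
    (5-min) and air pressure and temperature (30-min). Provides threshold
    light-level twilight annotation with unnatural-event flagging, solar
    geometry, a grid hidden-Markov positional posterior with probabilistic
    track bootstrapping, barometric altimetry and the twilight-ascent
    statistic, activity-based behaviour classification, annual-cycle phase
    assignment, gridded-weather annotation, and an ensemble of
    AR(1)-correlated binomial mixed models with an all-confidence-intervals
    relevance rule. A synthetic annual-cycle generator with ground truth and
    a co-registered weather grid makes the whole pipeline testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    nlme,
    geosphere,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
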