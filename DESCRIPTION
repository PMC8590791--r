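Package: wristpa
Title: Wrist Accelerometry Physical Activity Assessment and Methodological Analyses
Version: 0.1.0
Authors@R:
    person("wristpa", "developers", email = "dev@wristpa.invalid", role = c("aut", "cre"))
Description: A tested pipeline for assessing free-living physical activity
    from raw wrist-worn triaxial accelerometry: ENMO (Euclidean Norm Minus
    One) computation, 5-s epoch aggregation, variance-based non-wear
    detection, MET-anchored intensity classification (sedentary/LPA/MPA/VPA),
    bouted MVPA, wear-time validity rules, and daily summaries. On top of the
    pipeline it implements four methodological analyses: the accuracy of
    absolute intensity cut-offs relative to individual cardiorespiratory
    fitness (%VO2peak bands), linear mixed models for day-of-week, reactivity
    and season effects on daily activity, weekday/weekend sleep regression
    and wear-time comparisons, and the midpoint of the most active 10-h
    window of the day. A synthetic-data module generates raw signals and
    daily summary datasets with known ground truth so every stage is testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
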