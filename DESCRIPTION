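Package: periwear
Title: Compliance Analysis for Perioperative Activity-Tracker Data
Version: 0.9.0
Authors@R:
    person("Periwear", "Developers", email = "maintainer@periwear.dev",
           role = c("aut", "cre"))
Description: Tools for analysing daily wear compliance in step-count data
    collected from consumer activity trackers around ambulatory surgery.
    Aligns minute- or hour-resolution step records onto a 57-day
    perioperative grid (14 days before surgery through 42 days after),
    scores each patient-day against five valid-day criteria (>0 steps,
    >500 steps, >=10 active hours, 3-a-day windows, 3-of-4 six-hour
    windows), summarises compliance by patient, day, and two-week stage,
    quantifies between-criteria deviation, relates it to device placement
    and demographics via correlations and subject-random-intercept mixed
    models, renders hour-by-day activity heatmaps and daily compliance
    plots, and simulates synthetic perioperative cohorts with configurable
    wear behaviour, diurnal activity, post-surgical activity dip and
    recovery for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    lme4,
    scales,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
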