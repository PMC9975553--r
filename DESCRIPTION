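Package: isotempo
Title: Isotemporal Substitution Modelling of Accelerometer-Measured
    Physical Activity and Cardiometabolic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how reallocating time between sedentary
    behaviour and light, moderate and vigorous physical activity relates to
    cardiometabolic health in cohort data. Classifies 60-second tri-axial
    accelerometer count epochs into intensity bands by vector-magnitude cut
    points, builds a composite cardiometabolic risk z-score (CMR-z) with the
    protective-factor sign flip for HDL cholesterol, and fits the single,
    partition and isotemporal substitution regression models on per-10-minute
    exposures with covariate adjustment, including the full pairwise
    substitution matrix and linear duration scaling of substitution effects.
    A synthetic-cohort generator with planted substitution effects supports
    parameter-recovery testing and a reproducible end-to-end pipeline.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
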