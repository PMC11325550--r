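Package: transferlur
Title: Transfer-Learning Land-Use Regression for Hyperlocal Air Pollution Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Land-use regression (LUR) models for mapping hyperlocal air
    pollution in a target city without local measurements. Implements
    CORAL covariance alignment of predictor features from mobile-monitored
    source cities followed by ridge regression in the aligned space,
    inverse-distance-weighted fusion of per-source models, forward stepwise
    LUR baselines with sign constraints, mobile-monitoring preprocessing
    (range filtering, winsorizing, temporal correction, road-segment
    snapping, mean-of-means aggregation), buffer-based GIS predictor
    extraction, agreement metrics including Lin's concordance correlation
    coefficient, and a synthetic multi-city study generator with covariate
    and distance-decaying conditional shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    geosphere,
    MASS
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
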