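Package: swaycop
Title: Postural Sway Metrics and Center-of-Pressure Path Prediction from a
    Trunk Gyroscope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies quiet-stance postural sway from a trunk-worn triaxial
    gyroscope and evaluates how well those sway metrics predict the
    force-plate center-of-pressure (COP) path length. Implements the four
    windowed magnitude metrics (root-mean-square, range, area under the
    curve, summed absolute successive differences), COP path length, five
    regression learners (least-squares boosting, bagged trees, RBF support
    vector regression, a two-hidden-layer neural network, and Gaussian
    process regression) compared under k-fold cross-validation, and the
    method-agreement statistics used in concurrent-validity studies
    (Spearman's rho, ICC(2,1) with 95% CI, Bland-Altman limits of agreement,
    slope/offset). Ships an Ornstein-Uhlenbeck inverted-pendulum simulator
    that generates paired gyroscope/COP cohorts so the full pipeline is
    testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    ggplot2
Config/testthat/edition: 3
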