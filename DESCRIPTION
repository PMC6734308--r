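Package: fdrate
Title: Automated Quality Rating of AFM Force-Distance Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of atomic force microscopy (AFM)
    nano-indentation force-distance (FD) curves: tip-sample separation,
    baseline offset correction, contact-point retrieval, least-squares
    fitting of the spherical-indenter Hertz model (exact parametric
    solution and a power-series corrected parabolic approximation),
    extraction of quality-dependent features from fit residuals, and
    supervised rating of curve quality with tree-ensemble regressors.
    Includes ROC/MSE evaluation protocols, quality-based curve sorting,
    per-pixel stiffness and quality mapping for 2-D FD grids, and a
    synthetic FD-curve generator with controlled artifact injection
    (contact-point offset, indentation spikes, baseline tilt) for
    testing the full pipeline without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    ranger,
    xgboost,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
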