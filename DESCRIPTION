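Package: phenocue
Title: Identification and Predictive Evaluation of Temperature Cues for
    Phenological Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify the temperature cues that drive the timing of
    annual life-history events and to evaluate how well the identified cues
    predict. Implements exhaustive absolute and relative sliding-time-window
    searches with AICc model selection, climate sensitivity profiles with
    spline smoothing and quantile thresholding, penalized B-spline signal
    regression on a full year of daily temperatures, and a three-parameter
    growing degree-day thermal-time model fitted by simulated annealing with
    bootstrap percentile confidence intervals. A cross-validation framework
    computes mean absolute error, signed error, prediction-interval width and
    coverage, and the temporal trend in prediction error. A synthetic
    climate-phenology generator with known ground truth supports parameter
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    splines,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
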