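Package: yieldgaps
Title: Attainable Yields and Yield-Gap Trends from Census Panels by
    Area-Weighted Quantile Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits annual attainable-yield ("ceiling") surfaces to
    administrative-unit crop census panels with an area-weighted 95th-percentile
    quantile regression whose loss is regularized so the surface encompasses the
    intended share of harvested area.  Includes quality filtering of census
    records, derivation of biophysical covariates (growing degree days,
    precipitation concentration index, vernalization factor, irrigated
    fraction), stepwise model selection by leave-one-layer-out temporal
    cross-validation on half-decadal smoothed layers, bootstrap confidence
    intervals for coefficients and trends, yield-gap trend and time-to-closure
    analysis, a three-category typology of gap trajectories, piecewise
    stagnation detection, and a synthetic census-panel generator with known
    ground truth for end-to-end validation.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
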