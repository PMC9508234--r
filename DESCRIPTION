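Package: grasstrend
Title: Grassland Degradation Mapping, Driver Attribution and Persistence Forecasting from NDVI Raster Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing annual NDVI raster time series over grassland:
    per-year spatial heterogeneity (3x3-window coefficient of variation of NDVI),
    Theil-Sen slope and Mann-Kendall significance mapping, a six-level
    degradation/restoration classification, degradation hot-plot detection with
    the local Moran's I statistic, an improved residual-trend (RESTREND)
    attribution of NDVI and CV_NDVI dynamics to climate versus human drivers
    with per-pixel contribution rates and a twelve-scenario typology, and a
    rescaled-range (R/S) Hurst-exponent forecast of trend persistence. Includes
    a synthetic-scene generator with known per-pixel drivers (and an exact
    fractional-Gaussian-noise simulator) so every stage can be validated against
    ground truth, plus a single-config pipeline runner with reproducible,
    seedable outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    randomForest,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
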