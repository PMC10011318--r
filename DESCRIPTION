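Package: lakefuse
Title: Spatiotemporal Data Fusion of Multi-Source Lake Chlorophyll-a Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble Kalman filter and fixed-interval smoother for fusing
    routine grab samples, automatic-station fluorometry and satellite
    chlorophyll-a rasters on a gridded lake domain. The state is the
    log-transformed chlorophyll-a field with mean-reverting AR(1) dynamics and
    an isotropic spherical spatial covariance; observation errors are
    multiplicative and source-specific. Includes sensor and satellite
    calibration regressions, spherical variogram fitting for the spatial
    correlation length, a synthetic-data generator emulating a boreal lake
    monitoring season, and reporting products: station time series with 68%
    confidence intervals, daily concentration and relative-SD maps, and
    period summaries over the Water Framework Directive window.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
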