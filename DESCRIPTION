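Package: phenofill
Title: Gaussian-Process Gap-Filling and Crop Phenology for Vegetation Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs continuous vegetation-descriptor time series (for
    example leaf area index) from irregular, cloud-interrupted satellite
    acquisitions using exact Gaussian process regression with a squared
    exponential kernel. Per-pixel hyperparameter training by marginal
    likelihood maximisation can be replaced by precalculated per-crop or
    global hyperparameter averages, turning whole-scene reconstruction into a
    fixed-kernel fitting problem with shared covariance factorisations.
    Includes season detection and phenology indicators (start, end and length
    of season, day of maximum, amplitude, seasonal integrals), comparison
    statistics between parameterisations, and a synthetic multi-crop scene
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
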