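Package: nnmap
Title: Design-Based Nearest-Neighbor Spatial Interpolation and Bootstrap
    Error Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nearest-neighbor spatial interpolation for mapping continuous
    populations, finite populations of areas and finite populations of
    units from a design-based perspective, where the population is fixed
    and all uncertainty stems from the probabilistic sampling scheme.
    Implements the classical spatial designs used in environmental and
    forest surveys (uniform random sampling, tessellation stratified
    sampling, systematic grid sampling, simple random sampling without
    replacement, one-per-stratum stratified sampling, systematic sampling
    and probability-proportional-to-prediction sampling), finite-sample
    bounds on the design-based interpolation error driven by the local
    oscillation of the field and the probability that no sampled location
    falls near a target point, a pseudopopulation bootstrap estimator of
    the root mean squared error of the interpolated map, and a Monte-Carlo
    harness evaluating bias, RMSE and bootstrap calibration on canonical
    synthetic surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
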