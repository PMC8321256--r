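Package: vicomp
Title: Self-Supervised Compression of Satellite Vegetation-Index Time Series
Version: 0.1.0
Authors@R: person("vicomp", "developers", role = c("aut", "cre"),
    email = "vicomp@example.org")
Description: Tools for compressing high-dimensional satellite vegetation-index
    time series into a few latent features and evaluating them for vegetation
    type mapping. Computes sixteen spectral vegetation indices from six-band
    surface-reflectance scenes, aggregates them into per-pixel monthly median
    composites (a 192-feature annual vector), compresses the vectors with
    dense and one-dimensional convolutional autoencoders, and quantifies the
    discriminative power of the compressed features with a bootstrap-resampled
    random-forest protocol against a feature-importance baseline. Includes a
    synthetic scene generator with class-specific phenology so the full
    pipeline is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lattice,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
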