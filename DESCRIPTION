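Package: circmoran
Title: Spatial Autocorrelation of Phase Patterns in Oscillatory Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies spatio-temporal synchronization in oscillatory
    imaging data, such as circadian bioluminescence recordings, using
    Moran's I and a circular-statistics variant for instantaneous-phase
    fields. Provides sparse spatial weight matrices (von Neumann lattice
    neighborhoods, inverse-distance, distance bands), Monte-Carlo
    significance testing under resampling and randomization nulls,
    Hodrick-Prescott detrending, Hilbert-transform phase extraction, the
    Kuramoto order parameter, bimodal von Mises mixture fits to phase
    histograms, a two-dimensional lattice Kuramoto simulator, and
    synthetic fixture generators for binary grids, phase patterns and
    SCN-like oscillatory movies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
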