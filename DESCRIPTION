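Package: chromaquant
Title: Batch Processing and Quantitation of HPLC-FD Chromatograms
Version: 0.1.0
Authors@R:
    person("Analytical", "Informatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated processing of two-dimensional (time versus intensity)
    chromatograms from high-performance liquid chromatography with
    fluorescence detection. Provides parsers for common plain-text export
    dialects, background and noise estimation from the lowest-average
    sliding window, first-derivative spline peak detection with iterative
    Gaussian fit-and-subtract deconvolution, calibrant-based retention-time
    calibration with a second-degree polynomial, integration-based peak
    quantitation, per-analyte quality-control statistics (residual retention
    time, signal-to-noise, Gaussian peak quality), replicate batch
    aggregation with coefficients of variation, and a seeded synthetic
    chromatogram generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
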