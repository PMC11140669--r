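Package: ramanspec
Title: Integrative Raman Spectroscopy Data Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for Raman spectroscopic data analysis built around a
    uniform array-based spectral container for single spectra, spectra stacks,
    hyperspectral images and volumetric scans. Provides readers and writers for
    delimited-text spectra, MATLAB MAT-file exports and a native HDF5 layout; a
    preprocessing suite (spectral cropping, cosmic-ray removal via modified
    z-scores, Savitzky-Golay and Gaussian denoising, asymmetric and adaptive
    penalized least-squares baseline correction, normalization, background
    subtraction); composable and JSON-serializable preprocessing pipelines with
    a registry of named protocols; hyperspectral unmixing by N-FINDR endmember
    extraction and fully constrained least-squares abundance estimation;
    spectral comparison metrics (mean squared error, spectral angle distance,
    spectral information divergence); and a ground-truth-bearing synthetic
    Raman scene generator for validation. A command-line interface ties the
    modules into reproducible load-preprocess-analyze workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    rhdf5,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
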