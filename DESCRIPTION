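Package: scraman
Title: Simulation, Detection and Classification Pipeline for Single-Cell
    Raman Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free pipeline for high-throughput single-cell Raman
    phenotyping. Simulates fields of cells, their microscope images and Raman
    spectra (including Brownian drift between cell detection and laser
    pointing); detects single cells in field images by Sobel/Prewitt edge
    analysis with a conservative acceptance rule; performs Raman spectrum
    quality control (baseline correction, Savitzky-Golay smoothing and
    derivatives, Fourier low-pass filtering with apodization, normalization,
    signal-to-noise estimation); maintains a two-tier (raw/refined) spectral
    phenotype database with SNR-based promotion rules; classifies and searches
    spectra by nu-SVM with an RBF kernel, Euclidean-distance search and
    PCA-based two-strain separation; and benchmarks end-to-end sensitivity of
    image analysis and Raman profiling against simulator ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    Matrix,
    png,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
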