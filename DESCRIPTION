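Package: valvebench
Title: Bench-Top and Simulated Heart-Valve Performance Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for early-stage aortic-valve calcification
    studies that combine pulse-duplicator testing, nanoindentation and
    simulated leaflet hemodynamics. Computes the four ISO 5840-style
    hydrodynamic functionality metrics (regurgitant fraction, transvalvular
    pressure drop, root-mean-square flow and effective orifice area) from
    pressure/flow waveforms, fits the Hertzian contact model to
    nanoindentation load-displacement records to estimate Young's modulus,
    evaluates time-averaged wall shear stress, oscillatory shear index and
    Q-criterion vortex fields on leaflet surfaces and velocity grids,
    measures geometric orifice area by planimetry of valve-opening frames
    (CLAHE, Gaussian smoothing, thresholded region extraction and
    edge-based active-contour refinement), and reports the comparison
    statistics (skewness-kurtosis normality screening, pooled t-tests with
    tiered significance, symmetric percent-difference tables). A seeded
    synthetic-data module generates waveforms, indentation curves, wall
    shear fields, velocity grids and calibrated orifice images with known
    ground truth so every stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
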