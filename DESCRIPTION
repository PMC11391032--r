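Package: thrombochip
Title: On-Chip Calibrated Automated Thrombinography and Vessel
    Permeability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for thrombin-generation and permeability
    assays performed inside microfluidic organ-on-a-chip plates. Converts
    fluorescence time-lapse imaging of a fluorogenic thrombin substrate
    into calibrated thrombin concentration curves (inner-filter arctanh
    correction, Savitzky-Golay differentiation, calibrator-factor
    scaling) and extracts thrombogram parameters (lag time, peak,
    time-to-peak, endogenous thrombin potential, velocity index). Also
    computes apparent permeability coefficients from donor/receiver
    dextran traces, quantifies rendered immunofluorescence images
    (positive-cell fractions, spots per cell), and applies the assay's
    group statistics (1.5 IQR outlier removal, one-way ANOVA with
    Dunnett's test, fold changes). A synthetic-data module
    forward-simulates every input from known ground truth so inversion
    accuracy is measurable without real acquisitions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    multcomp,
    tiff,
    EBImage,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
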