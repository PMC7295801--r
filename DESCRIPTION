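Package: seasontl
Title: Seasonal Fourier Regression of Leukocyte Telomere Length from qPCR
    Plate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of season-of-conception effects on relative
    leukocyte telomere length. Converts raw monochrome multiplex qPCR plate
    readings into quality-controlled T/S ratios via per-plate standard
    curves, normalizes them with per-plate z-scores (optionally Box-Cox),
    and tests for seasonality of conception with Fourier-term (cosinor)
    linear regression compared by likelihood ratio tests, reporting
    amplitude and peak/nadir dates with bootstrap uncertainty. Includes
    a reference-based constrained-projection estimator of white-cell
    fractions for cell-composition adjustment, and a synthetic-cohort
    generator (cohorts, qPCR plates, cell mixtures, with ground truth)
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
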