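Package: whitenir
Title: Near-Infrared Transmittance Imaging Pipeline for Internal
    Whitening in Ginseng Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for near-infrared (900-1700 nm)
    transmittance hyperspectral images of ginseng roots, aimed at
    detecting and quantifying inner whitening, an internal disorder in
    which central tissue becomes optically dense. Provides ENVI
    hypercube input/output, dark/white reference calibration,
    background segmentation, per-pixel spectrum normalization,
    PCA-based characteristic waveband selection with per-band one-way
    ANOVA, two-band ratio imaging with threshold segmentation, a
    percent-whitening statistic with a three-sigma outlier screen, and
    a parametric phantom generator that plants whitened regions of
    known area fraction so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
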