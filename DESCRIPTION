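Package: furatrack
Title: Automated Calcium-Profile Extraction and Multi-Cell Tracking for
    Fura-2 Ratio Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-cell intracellular calcium profiles from
    dual-wavelength (340/380 nm excitation) Fura-2 fluorescence image
    sequences of endothelial monolayers. Builds the pixelwise ratio
    sequence, derives an area-calibrated processing window, segments each
    frame with Niblack local thresholding accelerated by integral images,
    tracks every selected cell across frames by mask intersection with a
    constant-acceleration Kalman filter to bridge transient disappearances,
    manages ONLINE/OFFLINE track reliability, and writes per-cell calcium
    profiles together with a per-frame tracked-cell density metric. A
    synthetic phantom generator with full ground truth supports validation
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
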