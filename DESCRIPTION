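Package: microquant
Title: Measurement Toolkit for Segmented Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Object-based measurement of segmented microscopy images (2D and 3D).
    Combines two independently segmented object sets with four overlap-resolution
    strategies (merge, preserve, discard, segment); provides a generalized
    thresholding engine in which any global method can run in adaptive (blockwise)
    mode, plus Sauvola local thresholding and an optional log-intensity transform;
    computes colocalization statistics including the Costes automated threshold
    with canonical, accurate, fast and faster (weighted bisection) search
    strategies; measures per-object Haralick texture using bounding-box cropping
    that is exactly equivalent to full-image masked computation; and measures 2D/3D
    object shape including image moments, inertia tensors, Euler number and
    solidity. Includes a deterministic synthetic-fixture generator and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
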