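Package: tipshape
Title: AFM Tip Shape Characterization and In Situ Wear Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing atomic force microscopy (AFM) tips from
    images of high-roughness polycrystalline surfaces. Implements height-map
    input/output (Gwyddion Simple Field, TIFF, CSV), line-by-line flattening and
    low-pass filtering, grayscale-morphology imaging (dilation/erosion) and
    blind tip reconstruction, apex geometry metrics (end radius by sphere fit,
    open sphericity, disc-method and worn volumes), and a fast in-situ
    tip-radius tracking method: parabolic fits of individual surface peaks in
    fast-axis line profiles, followed by maximum-likelihood decomposition of
    the peak-radius distribution into a normal (tip) plus lognormal (surface)
    convolution with profile-likelihood confidence intervals. A synthetic
    surface/tip/image simulator makes every stage testable without instrument
    data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
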