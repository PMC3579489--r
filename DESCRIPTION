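Package: mcrsims
Title: Multivariate Curve Resolution for Multi-Sample ToF-SIMS Image Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multivariate curve resolution (MCR) of large,
    multi-sample hyperspectral time-of-flight secondary ion mass
    spectrometry (ToF-SIMS) image data. Several image cubes are
    consolidated into a single pixels-by-channels matrix and decomposed
    by non-negativity-constrained alternating least squares (ALS) into
    concentration score images and pure-component spectra. The component
    range is bounded by a PCA scree evaluation; repeated random-start
    fits are consensus-clustered by k-means to seed one final ALS round;
    diagnostics cover over-fit detection, top-loaded-ion tables and
    per-sample component summaries. A synthetic phantom generator with
    known ground truth supports validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    yaml
Config/testthat/edition: 3
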