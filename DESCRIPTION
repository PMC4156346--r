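Package: dngrad
Title: Design and Validation of Digital Nanodot Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates digital nanodot gradients (DNGs) for surface
    micropatterning and haptotaxis assays. Dot layouts follow arbitrary
    monotonic or non-monotonic density profiles using either an ordered
    unit-cell algorithm or pseudo-random box seeding with an analytic
    compensation for the coverage lost to random dot overlap (a Boolean-model
    result). Includes raster-based density verification against the
    programmed profile, Ripley's K randomness testing with Monte-Carlo
    envelopes for complete spatial randomness, a design-versus-print overlay
    check with a synthetic print simulator, Caltech Intermediate Format (CIF)
    and bitmap export, and a parameter-table driven builder for gradient
    arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
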