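Package: ovocount
Title: Automatic and Semi-Automatic Counting of Mosquito Eggs in Strip Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Threshold-based counting of Aedes aegypti eggs in photographs of
    oviposition substrates. Dark eggs on a light background are segmented by a
    global grayscale threshold, grouped into connected components, and filtered
    by bounding-box area; objects larger than a single egg are flagged and
    their egg content estimated from the pixel-area ratio against a per-image
    single-egg reference. Includes a semi-automatic review workflow (CSV export
    of flagged objects, per-object corrections), calibration statistics against
    manual counts, dual-choice assay statistics, a seeded synthetic strip-image
    generator with exact ground truth, and a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jpeg,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
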