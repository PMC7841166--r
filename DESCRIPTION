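Package: FAProtrusion
Title: Longitudinal Protrusion Analysis of Focal Adhesion Proteins in
    Dual-Colour Super-Resolution Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures how far individual focal adhesion proteins protrude
    beyond their partner protein at the two ends of a focal adhesion, from
    dual-colour (red/green) super-resolution fluorescence images. Provides
    band-pass segmentation of adhesions, moment- and ridge-based fitting of
    the adhesion long axis, dual-channel intensity profiling with
    gap-tolerant run detection, pixel-geometry-aware length conversion,
    signed protrusion histograms with reference-bias correction and exact
    Mann-Whitney comparisons, 2D difference histograms with a
    cyan-white-magenta lookup table, stratification of adhesions by local
    membrane-edge motility, and a fully synthetic dual-channel scene
    generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: Software, CellBiology, Visualization, Segmentation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
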