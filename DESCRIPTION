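Package: decalogue
Title: Low-Level Psychophysical Batteries and Scoring for Image-Computable Vision Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates calibrated psychophysical stimulus batteries covering
    the basic adaptive properties of the retina-V1 pathway (spectral
    sensitivity, brightness and chromatic adaptation, contrast sensitivity,
    receptive fields, contrast response, and energy/frequency/orientation
    masking), drives arbitrary image-computable models through them with a
    configurable distance read-out, and scores the resulting response-curve
    families against packaged human ground truth using grouped Pearson
    correlation, Kendall rank correlation of curve orderings, plain-average
    aggregation with bootstrap intervals, and two-sample Kolmogorov-Smirnov
    model comparison. Two reference models (a linear control and a toy
    divisive-normalization cascade) are bundled to exercise the full
    pipeline without external weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
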