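Package: rppanorm
Title: Spatial Normalization and Quality Control for Reverse Phase Protein Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Corrects systematic spatial variation in reverse-phase protein
    array (RPPA) slides. Positive-control spots printed at regular intervals
    across a slide are used as anchors for a bilinear (optionally bicubic
    spline) interpolation of pseudo-positive-control intensities at every
    spot; the ratio of the interpolated surface to the mean positive-control
    intensity yields per-spot correction factors that are divided out of the
    measured intensities. Includes replicate-agreement quality metrics
    (percent coefficient of variation, Pearson correlation, Z'-factor,
    Welch t), a synthetic-slide simulator with known spatial bias fields for
    validating the correction, and readers and writers for MicroVigene-style
    spot quantification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
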