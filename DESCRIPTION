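Package: markerquant
Title: Quantification of Treatment-Target Marker Expression on Circulating Tumor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying treatment-target (HER-2) immunofluorescence
    on circulating tumor cell thumbnail images: restores archived 8-bit
    multi-channel TIFF thumbnails to their native 12-bit intensity scale,
    detects object contours per channel with a parameter-free multi-scale
    segmentation, extracts per-object intensity and shape features, classifies
    marker expression as negative, dim or bright, summarizes per-patient
    heterogeneity, and computes manual-versus-automatic correlation and
    inter-reader concordance statistics. Includes a synthetic-fixture
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    EBImage,
    igraph,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
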