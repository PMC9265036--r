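Package: fleacardio
Title: Cardiac Chamber Geometry and Physiology from Water Flea Heart Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for cardiac physiology in water fleas
    (Daphnia, Moina) from sequences of heart-chamber segmentation masks:
    chamber geometry by direct least-squares ellipse fitting, cardiac rhythm
    (heart rate and Poincare SD1/SD2 heart-rate variability) from the chamber
    area time series, and volumetric endpoints (stroke volume, ejection
    fraction, fractional shortening, cardiac output) under a prolate-spheroid
    chamber model. Includes pixel-wise segmentation evaluation (Dice, IoU,
    sensitivity, specificity), dataset preparation utilities (frame
    extraction, train/validation splitting, paired image-mask augmentation),
    a classical threshold segmentation baseline, and a synthetic
    beating-heart video generator with known ground-truth physiology so the
    whole pipeline is testable without microscope recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    igraph,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
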