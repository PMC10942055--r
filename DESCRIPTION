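Package: textoncaps
Title: Texton-Dense Capsule Networks for Small-Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A hierarchical capsule-network image classifier for small (32x32)
    RGB or grayscale images, aimed at textured biomedical imagery such as
    histopathology and MRI slices. Each of three hierarchic levels applies a
    six-texton detection operator (2x2 equal-pixel micro-structures) and an
    eight-layer densely connected convolution block before a primary-capsule
    convolution; four class-capsule heads are obtained by dynamic
    routing-by-agreement, trained jointly under per-head margin losses with a
    reconstruction decoder, and concatenated at test time into 54-dimensional
    class capsules. Includes IDX and image-folder dataset readers, a stratified
    80:20 split, translation/rotation augmentation, a synthetic textured-image
    generator for offline testing, and per-class evaluation metrics
    (confusion matrices, precision, sensitivity, specificity, per-class
    accuracy, ROC and precision-recall curves). All network layers and the
    training loop are implemented in base R.
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
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    pROC,
    optparse,
    tiff,
    jpeg
Config/testthat/edition: 3
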