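Package: blockcount
Title: Plant Counting from Dot Annotations by Blockwise Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plant density in field images from dot annotations by
    counting-by-classification: dot maps are smoothed into density maps,
    summed over overlapping patches into count maps, and quantized into
    log-spaced count-interval class maps. A fully convolutional network with
    multilayer feature fusion predicts the class of every overlapping patch;
    inverse quantization and coverage-weighted deredundancy decode the
    redundant class map back into a pixel-resolution count map whose sum is
    the per-image count. Includes a seeded generator of rice-like dotted
    scenes, a training loop with a count-regression ablation, and the
    standard counting metrics (MAE, RMSE, rMAE, R squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
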