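Package: tab2img
Title: Tabular-to-Image Encodings and a Compact CNN for Clinical Record
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 1-D numeric clinical records into 2-D images so that
    convolutional neural networks can classify tabular data.  Provides three
    encoders (equidistant bar graph, normalized distance matrix, and their
    3-channel combination), a covariance-rank feature-ordering optimizer
    (genetic algorithm with an exhaustive oracle), loaders for the UCI
    Wisconsin breast-cancer table dialects, a compact 4-block VGG-style CNN
    with an SGD-with-momentum trainer, the best/average multi-attempt
    experiment protocol, diagnostic evaluation (sensitivity, specificity,
    F1), and a class-conditional Gaussian simulator for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
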