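Package: fluorChill
Title: Chilling-Injury Grading and Classification from Chlorophyll
    Fluorescence Leaf Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Grades chilling (cold-stress) injury in pseudo-colored
    chlorophyll fluorescence leaf images by the injured-to-leaf area
    ratio, extracts 36 color and gray-level image features (color-space
    descriptors and their ratios, histogram statistics, gray-gradient
    co-occurrence and gray-level co-occurrence texture features),
    screens features by tie-corrected Spearman rank correlation with
    the injury grade, and classifies grades with a bidirectional LSTM
    whose learning rate, hidden size and L2 penalty are tuned by the
    dung beetle optimizer. Includes a seeded synthetic-image generator
    with ground-truth masks, macro-averaged confusion-matrix metrics,
    an end-to-end pipeline and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    farver,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
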