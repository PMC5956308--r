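Package: nailfold
Title: Automated Structure and Flow Measurement for Nailfold Capillaroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated measurement of nailfold capillary structure and
    red blood cell flow from high-frame-rate capillaroscopy video. Overlapping
    frames are registered by translation and composited into a still mosaic;
    distal-row capillaries are detected by multiscale ridge filtering, their
    apices localised, paths traced along both limbs, and per-point width and
    orientation measured; cell velocity is estimated by optical flow. The six
    per-nailfold parameters (capillary density, mean and maximum width, shape
    score, derangement score and mean flow velocity) feed group statistics:
    one-way ANOVA with Tukey's range test, ROC areas, and stepwise logistic
    regression with leave-one-out cross-validation separating systemic
    sclerosis from primary Raynaud's and healthy-control subjects. A software
    phantom generator with full ground truth supports validation of every
    stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
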