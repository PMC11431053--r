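Package: octex
Title: Multi-Scale Texture-Encoding Classification of Cervical OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of cervical optical coherence tomography (OCT)
    volumes into five clinical categories (inflammation, cyst, ectropion,
    high-grade squamous intraepithelial lesion, cervical cancer) with a
    convolutional network that combines a four-scale residual feature
    pyramid, a learnable texton-dictionary texture-encoding layer, and
    deeply supervised auxiliary classifiers. Includes a seeded synthetic
    OCT volume generator with class-conditional texture motifs and
    ground-truth lesion masks, multi-page TIFF volume input/output with
    sliding-window patch extraction, stochastic gradient descent training
    with cosine annealing and weighted oversampling, a cross-shaped
    threshold voting rule that lifts patch predictions to volume- and
    patient-level verdicts, clinical evaluation metrics with exact
    Clopper-Pearson intervals, and Grad-CAM heatmaps per scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
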