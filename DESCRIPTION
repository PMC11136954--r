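Package: epanet
Title: Encoder-Decoder Semantic Segmentation of Bean Seedlings and Weeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Semantic segmentation of field imagery into background, bean
    seedling and weed classes with EPAnet, an ERFnet-style encoder-decoder
    extended with parameter-free SimAM attention after each downsampler, a
    DO-Conv feature-pyramid connector (FDPN), a point-wise spatial attention
    (PSA) decoder head, and a coupled cross-entropy / Dice loss. Includes a
    complete segmentation metric suite (per-class precision, recall, F1, IoU,
    overall accuracy, mIoU, FWIoU), paired PNG image/mask dataset handling
    with nine offline augmentations, a deterministic synthetic crop/weed
    scene generator, and training, evaluation and prediction drivers built on
    a small reverse-mode automatic-differentiation engine with C++
    convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
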