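Package: histocae
Title: Convolutional-Autoencoder Patch Classification for Viable-Tumor
    Segmentation in Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patch-wise viable-tumor segmentation for gigapixel
    histopathology slides built around a convolutional autoencoder (CAE).
    Slides are tiled into non-overlapping 256x256 patches, a strided-
    convolution encoder/decoder pair is trained to reconstruct patches under
    a joint MSE + SSIM + MAE reconstruction loss, and a softmax classifier
    head fine-tuned from the trained encoder labels each patch tumor versus
    non-tumor. Patch predictions are assembled into whole-slide masks and
    scored with dice, precision, recall, F1 and accuracy. A multi-resolution
    variant fuses co-registered 5x/10x/20x patches, and the spatially
    arranged 16x16x64 bottleneck encodings provide a 12:1 compressed
    representation of a whole slide. Includes a deterministic synthetic
    slide generator so the whole pipeline can be exercised without external
    data, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
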