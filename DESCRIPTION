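Package: pisnet
Title: Lightweight MLP-CNN Hybrid Networks for Point-of-Care Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds, trains and evaluates lightweight encoder-decoder
    segmentation networks for point-of-care medical imaging (breast
    ultrasound, dermoscopy, histology tiles). The architecture combines
    three convolutional stages with tokenized MLP stages whose blocks mix
    features along dual diagonal axes (diagonal-axial MLP), a hybrid
    downsampling stage fusing linear and max-pooled feature paths, and a
    dynamic residual spatial pyramid pooling bottleneck whose kernel sizes
    adapt to the input resolution. All tensor operations and reverse-mode
    gradients are implemented in base R, so models are trainable without
    external deep-learning runtimes. Includes a paired image/mask data
    pipeline (loading, resizing, patch slicing, seeded splits), a seeded
    synthetic data generator emulating ultrasound, dermoscopy and nuclei
    modalities, Dice/BCE compound losses, IoU/Dice evaluation, and a
    command-line harness for training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
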