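Package: osdetr
Title: Orthogonal Channel-Shuffle Detection Components for Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks of an end-to-end lesion detector for medical
    images in the DETR (detection transformer) family: channel attention
    driven by frozen filters sampled from the special orthogonal group
    SO(n), channel-shuffle residual blocks and a multi-scale backbone, a
    hybrid encoder combining deformable attention on the deepest feature
    plane with convolutional cross-scale fusion, an interior-aware
    corner-distance IoU (IACD-IoU) score and loss for bounding-box
    regression, a query-based decoder with denoising groups and Hungarian
    matching, COCO-style average-precision evaluation, and a synthetic
    lesion-scene generator so every stage is testable at desk scale. The
    trainable modules run on a small reverse-mode automatic
    differentiation tape included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
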