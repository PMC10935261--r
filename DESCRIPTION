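Package: dtsdistill
Title: Dual-Teacher Supervised Decay Knowledge Distillation for Small Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements dual-teacher knowledge distillation with supervised
    decay (DTSD) for image classification: element-wise maximum fusion of two
    teachers' temperature-softened predictive distributions, sigmoid-scheduled
    temperature and loss-mixing weight that shift emphasis from hard labels to
    teacher soft labels as training progresses, and a Jensen-Shannon divergence
    soft loss. Ships a desk-scale training and evaluation harness built around
    a small convolutional network registry, an occlusion-style image
    augmentation stack (cutout, random erasing, hide-and-seek, probability
    combined photometric/geometric sub-strategies), a procedural synthetic
    image dataset generator with stratified splitting, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
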