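Package: stagenet
Title: Lightweight Growth-Stage Object Detection for Strawberry Phenology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A lightweight single-stage object detector for the five phenological
    stages of greenhouse strawberries (flowering, young fruit, fruit expansion,
    colour turning, maturation). Provides a synthetic stage-labelled scene
    generator with YOLO-txt and Pascal VOC XML annotation I/O, photometric and
    geometric augmentation operators, a mobile inverted-bottleneck backbone
    emitting a three-level feature pyramid, a fusion neck with DySample adaptive
    upsampling, reparameterizable RepNCSPELAN4 aggregation and iRMB windowed
    attention, an anchor-free detection head trained with an Inner-IoU bounding
    box loss, mAP@0.5 evaluation, a parameter/FLOP audit, and Grad-CAM++
    explanations. All network computation runs on an in-package reverse-mode
    autodiff engine with compiled convolution kernels, so the full pipeline is
    testable on a plain CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    xml2,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
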