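Package: cenkd
Title: Compressed EfficientNet Students with Knowledge Distillation for
    Small Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and trains very small convolutional image classifiers
    by compressing the EfficientNetB0 entry block into a sub-20K-parameter
    backbone, fusing two independently initialized copies of it by
    element-wise feature addition, and appending a lightweight residual
    skip block that uses a 1x1 depthwise convolution, a pointwise
    convolution and the self-normalizing SeLU activation. Training
    supports plain supervised learning and knowledge distillation with a
    temperature-scaled softmax and a weighted soft/hard loss. Includes an
    analytic parameter and FLOPs cost model for declarative model graphs,
    per-class one-vs-rest evaluation metrics, a procedural 6-class
    synthetic image generator for dependency-free testing, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
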