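Package: sadagrad
Title: Scheduled Adagrad Optimization with a Synthetic Histology-Texture
    Benchmark
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: From-scratch implementations of four stochastic first-order
    optimizers -- SGD, Adagrad, Adam, and SAdagrad, a scheduled variant of
    Adagrad that combines a per-epoch learning-rate table with a step-size
    floor so the effective rate cannot vanish as the squared-gradient
    accumulator grows -- together with coupled L2 weight decay and
    frozen-parameter fine-tuning. Includes a full multiclass evaluation
    suite (confusion matrices, per-class and micro/macro/weighted
    precision/recall/F1, one-vs-rest ROC and AUC), a synthetic eight-class
    colorectal-tissue texture-patch generator with the usual augmentation
    operators (flips, right-angle rotations, zoom-crop, color jitter,
    probabilistic grayscale), a small classifier with exact analytic
    gradients for benchmarking the optimizers end to end, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    caret,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
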