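Package: actsign
Title: Activation-Function Benchmarking for a Compact Brain-MRI CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A compact convolutional neural network for four-class brain-MRI
    tumor classification, built around nine pluggable scalar activation
    functions including a rectified softsign nonlinearity (softsign composed
    with ReLU).  Provides closed-form derivatives for every activation, a
    declarative network builder with a learnable-parameter audit, a synthetic
    phantom-image generator that emulates the four tumor classes, a seeded
    Adam training loop with cross-entropy loss, multiclass evaluation metrics
    (confusion matrix, precision/recall/F1, one-vs-rest ROC and AUC), and
    Grad-CAM class activation maps for visual explanation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
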