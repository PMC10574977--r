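Package: trustauc
Title: Trustworthy Class-Imbalanced Image Classification via Contrastive
    Pre-Training and AUC Margin Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building trustworthy binary image
    classifiers under heavy class imbalance. Provides a synthetic
    chest-radiograph-like image simulator, contrastive self-supervised
    pre-training of a convolutional encoder with the normalized-temperature
    (NT-Xent) loss, supervised fine-tuning with a min-max margin surrogate
    for the area under the ROC curve (deep AUC maximization) optimized by
    primal-dual stochastic gradients, question-answer trust quantification
    with F1-optimal threshold calibration and confidence normalization,
    per-class performance metrics, penultimate-layer embedding extraction,
    gradient-weighted class activation maps (Grad-CAM), and an
    orchestration layer for ablation arms and stratified k-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
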