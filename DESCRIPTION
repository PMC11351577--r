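Package: qlung
Title: Hybrid Quantum-Classical Classification of Lung Lesions from Paired CXR/CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end hybrid quantum-classical pipeline for three-class
    (normal/benign/malignant) lung lesion classification from paired chest
    radiograph (CXR) and computed tomography (CT) images. Provides a synthetic
    paired-modality phantom generator, a small trainable convolutional feature
    extractor, cross-modality feature fusion by concatenation, SVD compression
    to five quantum features, a from-scratch statevector simulator with
    parameter-shift gradients, a five-qubit variational circuit layer, a dense
    classification head, joint training with a no-quantum ablation baseline,
    and a full evaluation suite (confusion matrices, sensitivity, specificity,
    precision, F1, MCC, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
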