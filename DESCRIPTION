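Package: protlm
Title: Transfer Learning for Protein Sequence Classification with
    Regularized LSTM Language Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pre-trains a regularized three-layer LSTM language model on
    unlabeled amino-acid sequences and fine-tunes it, with a concat-pooling
    classifier head, gradual unfreezing and one-cycle learning-rate
    scheduling, on protein classification tasks (enzyme-class, multi-label
    gene-ontology and per-dataset remote-homology protocols). Includes
    cluster-aware train/validation/test splitting with redundancy control
    and training-set subsampling, a position-specific scoring matrix (PSSM)
    plus one-hot convolutional baseline with leakage-controlled PSSM
    databases, protein-centric evaluation metrics (accuracy, mean F1, Fmax,
    Smin, AUPR, AUC, AUC50), per-residue attribution by integrated
    gradients and X-occlusion, and a synthetic motif-family sequence
    generator so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
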