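Package: distinctcv
Title: Distinctness-Aware Cross-Validation for Gene-Expression Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how distinct a cross-validation test set is from its
    training set via the harmonic mean of min-max-normalized Euclidean
    distances between condition-level transcription-factor expression
    profiles, and generates cross-validation partition collections spanning
    a spectrum of distinctness: random K-fold (RCV), clustered K-fold with
    k-means folds (CCV), and simulated-annealing-optimized partitions
    (SACV). Includes an evaluation harness for expression-to-expression
    regression (least-angle-style lasso, elastic net, RBF support vector
    regression) that relates estimated prediction accuracy to train/test
    distinctness, plus a synthetic-data generator emulating clustered
    transcriptomic conditions with context-specific regulatory effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
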