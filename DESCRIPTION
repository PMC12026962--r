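Package: anesgraph
Title: Post-Anesthesia Brain-State Classification on Sample-Similarity Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies post-anesthesia brain states (wakefulness, sleep
    stages, unresponsive wakefulness and related conditions) from small,
    imbalanced tables of thalamic and tissue activation features. Merges
    per-study feature tables, augments minority classes with SMOTE
    interpolation, converts samples into an undirected similarity graph
    weighted by Spearman rank correlation (with cosine and Euclidean
    alternatives), classifies nodes transductively with a message-passing
    neural network built from feed-forward blocks with skip connections,
    and evaluates predictions with a full multiclass panel (sensitivity,
    precision, specificity, NPV, FPR, FDR, FNR, F1, MCC, Cohen's kappa).
    Includes a seeded synthetic-cohort generator, a greedy hyperparameter
    ablation runner, an edge-threshold sweep, and oversampling and
    edge-weighting comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
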