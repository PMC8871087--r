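Package: csknn
Title: Cost-Sensitive k-Nearest Neighbours with Entropy Features for
    Imbalanced Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Entropy-based feature extraction (approximate, sample, fuzzy
    and information entropy) for per-sample serum-protein marker panels,
    and a cost-sensitive k-nearest-neighbour classifier for heavily
    class-imbalanced clinical data.  Misclassification costs are derived
    from class-count ratios, class probabilities are smoothed by
    m-estimation towards the training priors, and predictions minimise
    expected misclassification cost.  Includes confusion-matrix metrics,
    ROC/AUC by dichotomisation, jackknife (leave-one-out) and stratified
    k-fold evaluation harnesses, a synthetic panel generator with
    class-controllable sequence regularity, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
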