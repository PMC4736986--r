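Package: tdmnorm
Title: Training Distribution Matching for Cross-Platform Expression
    Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Normalizes RNA-seq expression data so that machine-learning
    models trained on microarray data can be applied to it.  The core
    method, Training Distribution Matching (TDM), summarizes the training
    distribution's spread (the ratio of the tail spread above the third
    quartile, and below the first quartile, to the interquartile range)
    and maps the test data into the training range accordingly.  The
    package also provides the comparator transforms usually evaluated
    against TDM (quantile normalization to a target distribution, the
    Winsorized nonparanormal transform, and a plain log2 transform), a
    synthetic-data generator emulating condition-structured microarray
    data with a matched high-dynamic-range RNA-seq-like duplicate and a
    graded noise ladder, and an evaluation harness (partitioning around
    medoids with nearest-medoid assignment of new samples, L1-regularized
    multinomial classification with cross-validation, cluster-majority
    accuracy, balanced accuracy, Cohen's kappa, the no-information rate,
    a between/within distribution-variability score, and mean Kendall
    tau between matched samples).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
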