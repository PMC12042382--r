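Package: qsiraug
Title: Self-Distillation and Expert-Guided Data Augmentation for
    Assay-Interference Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving quantitative structure-interference
    relationship (QSIR) classifiers on heavily imbalanced compound sets by
    iterative teacher-student self-distillation. A balanced random forest on
    Morgan fingerprints is used to steer goal-directed molecule generation;
    candidate molecules are selected with active-learning acquisition
    functions (random, greedy, EPIG, and expert-combined variants),
    pseudo-labeled, and fed back into the training set. Includes a synthetic
    benchmark generator with planted reactive substructures, the full
    evaluation suite (MCC, enrichment factor, imbalance rate, internal
    diversity, PAINS alerts, QED, scaffold similarity), and model-similarity
    analysis via centered kernel alignment on random-forest leaf kernels.
    Molecule handling is backed by Open Babel and ChemmineR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ranger,
    jsonlite,
    yaml,
    ChemmineR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: Open Babel (obabel on the PATH)
Config/testthat/edition: 3
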