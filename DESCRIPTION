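Package: acustyle
Title: Style and Disease Effects in Acupuncture Point Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how acupuncture-point (AP) prescriptions vary with
    the prescribing style of a textbook versus the disease being treated.
    Builds per-document AP-score (relative frequency over the point
    vocabulary) and AP attribute-score matrices (distant, extra-meridian,
    five-transport, source point fractions), tests style and disease
    effects with a label-permutation test on the mean within-group
    Euclidean distance (empirical p-values, Benjamini-Hochberg
    correction), characterises structure by hierarchical clustering,
    metric multidimensional scaling with an RBF-SVM separability score,
    and document-similarity networks at multiple sparsity levels, and
    attributes style differences to theoretical point attributes via
    random-forest contribution scores and paired Wilcoxon signed-rank
    tests. Includes a seeded synthetic-corpus generator with planted
    style and disease effects for calibration and power analysis, and a
    packaged WHO-standard point attribute reference table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    ranger,
    e1071,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    broom
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
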