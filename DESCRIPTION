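Package: topoqspr
Title: Degree-Based Topological Indices and QSPR Models for Bladder-Cancer Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes ten degree-based topological indices (Zagreb, harmonic,
    forgotten, atom-bond connectivity, Randic, sum-connectivity,
    geometric-arithmetic, hyper-Zagreb and related descriptors) from
    hydrogen-suppressed molecular graphs via their degree-based edge
    partitions, and uses them in a quantitative structure-property
    relationship (QSPR) study of 17 bladder-cancer drugs: single-descriptor
    linear and cubic least-squares models with a full statistics panel, a
    small feedforward neural network (two hidden layers of 32 rectified
    linear units) trained by backpropagation, and exact Shapley-value
    attribution of predictions to descriptors. Includes the packaged drug
    data tables, a synthetic-data generator for chemical-like bounded-degree
    graphs with known ground-truth property models, and an end-to-end
    report driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
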