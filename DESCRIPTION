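Package: bnstability
Title: Stability of Boolean Networks Inferred from Expression Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how the robustness of a signaling pathway differs
    between two phenotype groups using Boolean network models inferred from
    gene expression time series. Real-valued series are binarized with a
    step-function (BASC A style) threshold placed at the strongest
    discontinuity of dynamic-programming-optimal step functions, with a
    seeded bootstrap significance test. Candidate Boolean functions per gene
    are inferred by the best-fit extension of partially defined Boolean
    functions; concrete synchronous networks are sampled uniformly from the
    candidate sets (probabilistic-network semantics) and perturbed by
    temporary single-bit state flips. Robustness is summarized as the
    normalized Hamming distance between perturbed and unperturbed
    trajectories after one and five synchronous transitions, starting from
    random, successor, and attractor states, and compared between groups by
    Wilcoxon rank-sum tests. A synthetic-study generator emulating a
    two-group muscle aging microarray design makes the whole pipeline
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
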