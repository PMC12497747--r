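Package: monoconn
Title: Monotone Trends in Graph-Theoretic Summaries of Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Screens epoch-wise functional-connectivity graphs from
    block-design task fMRI for monotone change across task iterations.
    Builds full (unthresholded) Fisher-Z weighted graphs per condition and
    iteration, computes weighted betweenness centrality rank orders and
    average shortest path length on inverted-weight distances, classifies
    8-point trajectories for weak monotonicity (with a one-violation
    relaxation), and screens group-averaged trajectories with an
    exact-permutation Spearman trend test. Includes a synthetic cohort
    generator with planted hub drift and group coupling offsets for
    validating the whole pipeline against known ground truth, plus a
    three-way mixed ANOVA for network efficiency and behavioral
    monotone-proportion comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
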