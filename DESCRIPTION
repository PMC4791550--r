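Package: ctbnflow
Title: Continuous-Time Bayesian Network Inference for Time-Course Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers gene regulatory networks from case/control time-course
    expression data with continuous-time Bayesian networks (CTBNs). Provides a
    synthetic microarray-like data generator driven by a known ground-truth
    CTBN (Gillespie trajectory simulation, uneven 72-hour sampling grids,
    log2-scale measurement noise), a preprocessing pipeline (normalization,
    detection and variability filters, per-time-point differential expression
    with Benjamini-Hochberg correction, three-bin fold-change discretization),
    a Bayesian structure learner (marginal-likelihood family score under
    Gamma/Dirichlet priors, greedy hill-climbing and exhaustive search,
    conditional-intensity-matrix posterior means), and network interpretation
    tools (hub ranking by out-degree, root/intermediate/leaf hierarchy,
    subnetwork extraction, directed-arc precision/recall/F1 scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
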