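Package: netcontrast
Title: Condition Contrasts on Weighted Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for contrasting task conditions on weighted
    functional brain networks. Computes participation coefficient,
    betweenness centrality, global efficiency and Newman spectral
    modularity over a proportional-threshold (cost) sweep of per-subject
    connectivity matrices, fits mass-univariate linear mixed-effects
    contrasts with FDR correction across nodes, and classifies conditions
    with a permutation-tested, stratified nested cross-validated linear
    support vector machine with z-scored feature-weight selection. Includes
    a synthetic-connectome generator with planted within-network condition
    effects so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
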