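Package: fcgraph
Title: Graph-Theoretic Analysis of Resting-State Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("fcgraph", "developers", email = "fcgraph@example.org", role = c("aut", "cre"))
Description: Pipeline for graph-theoretic analysis of resting-state fMRI
    functional connectivity in whole-brain and regulatory subnetworks:
    maximal-overlap discrete wavelet transform (MODWT) scale-2 correlation
    matrices, minimum-spanning-tree anchored proportional thresholding across
    a 50%-5% sparsity sweep, modularity, participation coefficient, degree
    centrality, hub prevalence and the hub distribution index (HDI), AUC
    aggregation over sparsities, mean-connectivity nuisance regression, and
    permutation-based group inference with FDR control.  Includes a synthetic
    cohort generator with planted modular and hub structure and clinical
    covariates for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
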