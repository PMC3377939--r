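Package: preclustsurv
Title: Penalized Cox Survival Models with Preclustered Gene Groups as Covariates
Version: 0.1.0
Authors@R:
    person("Preclustsurv", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates Cox proportional hazards survival models whose
    genomic covariates are single genes, gene groups (for example Gene Ontology
    biological-process groups), or correlated subclusters obtained by
    preclustering the genes of each group.  Preclustering uses partitioning
    around medoids on the 1 - Pearson-correlation dissimilarity with the number
    of clusters chosen by maximum mean intra-cluster correlation.  Gene sets are
    summarized by their first principal component.  Models are fitted by L1- or
    L2-penalized partial likelihood with unpenalized mandatory clinical
    covariates, the penalty tuned by cross-validated partial likelihood, and
    evaluated on repeated 2:1 train/test splits by the logrank test, a
    prognostic-index likelihood-ratio test and the IPCW (integrated) Brier
    score.  A synthetic-data module generates expression matrices with
    block-correlated subclusters nested in overlapping gene groups together
    with Cox-model survival times, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
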