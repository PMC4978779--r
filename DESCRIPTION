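Package: pofm
Title: Proportional-Odds Finite-Mixture Models for Ordinal Biclustering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based one- and two-mode clustering (biclustering) of
    matrices of ordered categorical responses, such as subjects-by-items
    Likert questionnaires.  Rows and/or columns are modelled as finite
    mixtures whose components shift the cumulative logits of a
    proportional-odds model, with optional row-by-column cluster
    interactions.  Models are fitted by an EM algorithm with a mean-field
    variational approximation for the two-mode case and a Newton-type
    maximiser of the complete-data log-likelihood, with multiple random
    restarts.  Includes ten likelihood-based information criteria for
    choosing the number of clusters, an ordinal-matrix simulator,
    replication drivers for model-selection and cluster-recovery
    simulation studies, and Rand-index evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
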