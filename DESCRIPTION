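Package: irmfa
Title: Structurally Constrained Factor Models of Brain Coactivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step analysis of structural and functional brain connectivity.
    Step one fits an infinite relational model (Chinese restaurant process prior,
    Dirichlet compound multinomial likelihood) to a streamline-count matrix by
    Markov chain Monte Carlo, recovering the number of clusters, cluster
    memberships, a binary region-to-region connectivity graph, and within- and
    between-cluster connection probabilities. Step two uses the recovered
    clusters as latent factors in maximum-likelihood factor models of functional
    correlation matrices: exploratory factor analysis with oblique target
    rotation toward the cluster pattern, and confirmatory factor analysis with
    cross-loadings fixed to zero. Includes synthetic-data generators for the
    standard simulation conditions, recovery metrics, model-fit indices (SRMR,
    RMSEA), task-versus-rest contrasts of factor correlations, and an
    L1-penalized link from factor correlations to behavioral outcomes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
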