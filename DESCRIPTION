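Package: p2net
Title: Bayesian p2 Random Graph Modelling of Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the undirected p2 exponential random graph model to
    biological networks: a dyad-independent logistic model with a global
    density parameter and node-level random-effect sociality parameters,
    optionally regressed on nodal covariates such as intrinsic protein
    disorder. Provides a Metropolis-within-Gibbs sampler with conjugate
    precision updates, Geweke and Gelman-Rubin convergence diagnostics,
    posterior summaries with social-node calling, posterior-predictive
    goodness-of-fit on the degree distribution, synthetic-network
    generation, and complete-linkage clustering of socialities with
    inter-cluster interaction flows.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
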