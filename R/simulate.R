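#' Simulate an undirected network from the p2 edge law
#'
#' Every unordered node pair is connected independently with probability
#' `expit(theta + alpha_i + alpha_j)`. The result is a simple undirected
#' graph; runs are reproducible under `set.seed()`.
#'
#' @param theta global density parameter.
#' @param alpha numeric vector of node socialities.
#' @param node_ids node identifiers; defaults to `v1..vn`.
#' @return a `p2_network`.
#' @export
simulate_network <- function(theta, alpha,
                             node_ids = paste0("v", seq_along(alpha))) {
  n <- length(alpha)
  if (n < 2L) stop("need at least 2 nodes")
  stopifnot(length(node_ids) == n, is.finite(theta), all(is.finite(alpha)))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- stats::plogis(theta + alpha[pairs[, 1L]] + alpha[pairs[, 2L]])
  on <- stats::runif(nrow(pairs)) < p
  edges <- cbind(node_ids[pairs[on, 1L]], node_ids[pairs[on, 2L]])
  p2_network(node_ids, edges)
}

#' Generate a synthetic study from the model's own generative law
#'
#' Draws a binary nodal covariate `g_i ~ Bernoulli(prevalence)`, random
#' effects `a_i ~ Normal(0, sigma_a^2)`, sets socialities
#' `alpha_i = gamma g_i + a_i`, and simulates the network from the p2
#' edge law. The defaults emulate the scale of a high-confidence human
#' protein interaction map: 401 nodes, density parameter -5.68, a weak
#' positive disorder effect 0.06, covariate prevalence 0.32 (130/401),
#' and unit random-effect spread.
#'
#' @param n number of nodes.
#' @param theta true density parameter.
#' @param gamma true covariate effect (scalar).
#' @param sigma_a standard deviation of the random effects, >= 0.
#' @param prevalence Bernoulli probability of the binary covariate.
#' @param seed integer seed.
#' @return an object of class `p2_study`: `network`, `covariates` (one
#'   binary column `disorder`), `truth` (a [p2_params()] plus the true
#'   alpha), and `seed`.
#' @export
generate_synthetic_study <- function(n = 401, theta = -5.68, gamma = 0.06,
                                     sigma_a = 1.0, prevalence = 0.32,
                                     seed = 1) {
  if (n < 2L) stop("need at least 2 nodes")
  stopifnot(sigma_a >= 0, prevalence >= 0, prevalence <= 1)
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  g <- as.numeric(stats::runif(n) < prevalence)
  a <- stats::rnorm(n, 0, sigma_a)
  alpha <- gamma * g + a
  net <- simulate_network(theta, alpha, ids)
  cov <- data.frame(disorder = g, row.names = ids)
  class(cov) <- c("p2_covariates", "data.frame")
  truth <- p2_params(theta = theta, gamma = gamma, a = a,
                     tau_theta = 1,
                     tau_gamma = 1,
                     tau_a = if (sigma_a > 0) sigma_a^-2 else Inf_guard())
  structure(list(network = net, covariates = cov, truth = truth,
                 alpha = alpha, seed = seed),
            class = "p2_study")
}

# sigma_a = 0 has no finite precision; store a large one so the truth
# record remains a valid parameter object
Inf_guard <- function() 1e12

#' @export
print.p2_study <- function(x, ...) {
  cat(sprintf(
    "p2_study: %d nodes, %d edges (seed %d); truth theta = %.2f, gamma = %.2f\n",
    length(x$network$nodes), nrow(x$network$edges), x$seed,
    x$truth$theta, if (length(x$truth$gamma)) x$truth$gamma else NA))
  invisible(x)
}

#' Posterior-predictive goodness-of-fit on the degree distribution
#'
#' Draws `n_sims` posterior samples (uniformly across chains and
#' iterations), simulates one network from each on the observed node
#' set, and tabulates the fraction of nodes at every degree value from 0
#' to the largest degree seen in the observed or simulated networks. The
#' observed degree-fraction curve is reported next to the 2.5%, 50% and
#' 97.5% quantiles of the simulated curves, plus an indicator of
#' envelope coverage per degree.
#'
#' @param samples a `p2_samples` object.
#' @param net the observed `p2_network`.
#' @param covariates aligned covariates used in the fit (or `NULL`).
#' @param n_sims number of simulated networks (default 100).
#' @return data frame of class `p2_gof` with columns `degree`,
#'   `observed_fraction`, `sim_q2.5`, `sim_median`, `sim_q97.5`,
#'   `inside_envelope`; the full simulation matrix is kept in the
#'   `"sims"` attribute.
#' @export
posterior_predictive_gof <- function(samples, net, covariates = NULL,
                                     n_sims = 100) {
  stopifnot(n_sims >= 1)
  covariates <- align_covariates(net, covariates)
  n <- length(net$nodes)
  X <- covariate_matrix(covariates, n)
  n_keep <- length(samples$chains[[1L]]$theta)
  obs_deg <- degree_sequence(net)
  sim_degs <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    ci <- sample.int(length(samples$chains), 1L)
    di <- sample.int(n_keep, 1L)
    ch <- samples$chains[[ci]]
    alpha <- ch$a[di, ]
    if (ncol(X) > 0L) alpha <- alpha + drop(X %*% ch$gamma[di, ])
    sim <- simulate_network(ch$theta[di], alpha, net$nodes)
    sim_degs[[s]] <- degree_sequence(sim)
  }
  max_deg <- max(c(obs_deg, unlist(sim_degs)))
  degs <- 0:max_deg
  frac <- function(d) tabulate(d + 1L, nbins = max_deg + 1L) / length(d)
  obs_frac <- frac(obs_deg)
  sims <- t(vapply(sim_degs, frac, numeric(max_deg + 1L)))
  colnames(sims) <- degs
  qs <- apply(sims, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  out <- data.frame(
    degree = degs,
    observed_fraction = obs_frac,
    sim_q2.5 = qs[1L, ],
    sim_median = qs[2L, ],
    sim_q97.5 = qs[3L, ]
  )
  out$inside_envelope <- out$observed_fraction >= out$sim_q2.5 &
    out$observed_fraction <= out$sim_q97.5
  attr(out, "sims") <- sims
  class(out) <- c("p2_gof", "data.frame")
  out
}

#' Write a goodness-of-fit table to CSV
#' @param gof a `p2_gof` table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gof <- function(gof, path) {
  utils::write.csv(as.data.frame(gof), path, row.names = FALSE)
  invisible(path)
}

#' Credible-interval coverage over simulated replicates
#'
#' The simulate-fit-check harness: for each replicate a synthetic study
#' is generated, the model is fitted, and the 95% posterior interval of
#' each global parameter is checked against the generating truth.
#' Replicates pool chains unconditionally (coverage is measured across
#' replicates, not gated per fit).
#'
#' @param replicates number of simulate-fit replicates, >= 1.
#' @param n,theta,gamma,sigma_a,prevalence study conditions passed to
#'   [generate_synthetic_study()].
#' @param config a [sampler_config()]; its seed is re-derived per
#'   replicate from `seed`.
#' @param seed master seed.
#' @return data frame of class `p2_recovery`: one row per parameter with
#'   `covered`, `replicates`, `coverage` and its binomial Monte Carlo
#'   standard error; per-replicate detail in the `"detail"` attribute.
#' @export
recovery_experiment <- function(replicates = 20, n = 80, theta = -2.5,
                                gamma = 0.7, sigma_a = 0.8,
                                prevalence = 0.3,
                                config = sampler_config(profile = "desk"),
                                seed = 1) {
  stopifnot(replicates >= 1)
  set.seed(seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  chain_master <- sample.int(.Machine$integer.max - 1L, replicates)
  detail <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    study <- generate_synthetic_study(n = n, theta = theta, gamma = gamma,
                                      sigma_a = sigma_a,
                                      prevalence = prevalence,
                                      seed = study_seeds[r])
    cfg <- config
    cfg$seed <- chain_master[r]
    fit <- run_chains(study$network, study$covariates, config = cfg)
    sm <- summarize_fit(fit, study$network, study$covariates, force = TRUE)
    g <- sm$global
    detail[[r]] <- data.frame(
      replicate = r,
      parameter = g$parameter,
      truth = c(theta, rep(gamma, nrow(g) - 1L)),
      q2.5 = g$q2.5, q97.5 = g$q97.5,
      covered = g$q2.5 <= c(theta, rep(gamma, nrow(g) - 1L)) &
        c(theta, rep(gamma, nrow(g) - 1L)) <= g$q97.5
    )
  }
  detail <- do.call(rbind, detail)
  agg <- stats::aggregate(covered ~ parameter, detail, sum)
  agg$replicates <- replicates
  agg$coverage <- agg$covered / replicates
  agg$mc_se <- sqrt(agg$coverage * (1 - agg$coverage) / replicates)
  attr(agg, "detail") <- detail
  class(agg) <- c("p2_recovery", "data.frame")
  agg
}

#' Write a synthetic study to disk
#'
#' Emits the edge list (TSV), the node covariate table (TSV, id column
#' first) and the generating truth (JSON if jsonlite is available,
#' otherwise a plain-text dump).
#'
#' @param study a `p2_study`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(study$network, file.path(dir, "edges.tsv"))
  tab <- cbind(id = rownames(study$covariates),
               as.data.frame(study$covariates))
  utils::write.table(tab, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(theta = study$truth$theta, gamma = study$truth$gamma,
                sigma_a = 1 / sqrt(study$truth$tau_a), seed = study$seed)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(utils::stack(truth)[, 2:1],
                       file.path(dir, "truth.txt"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
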