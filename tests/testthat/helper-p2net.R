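# Shared fixtures and independent oracles for the test suite. Everything
# is built in code; no data files.

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# triangle on A, B, C
triangle_network <- function() {
  p2_network(c("A", "B", "C"),
             rbind(c("A", "B"), c("B", "C"), c("A", "C")))
}

# a hand-rolled posterior-sample container: one or more chains of given
# scalar theta draws, node random-effect draw matrices and (optionally)
# covariate-effect draws
fake_samples <- function(theta, a, gamma = NULL, chains = 1L) {
  a <- as.matrix(a)
  n_keep <- nrow(a)
  if (is.null(gamma)) {
    gamma <- matrix(numeric(0), n_keep, 0L)
  } else {
    gamma <- as.matrix(gamma)
  }
  one <- function(shift = 0) {
    list(theta = rep_len(theta, n_keep) + shift,
         gamma = gamma, a = a,
         tau_theta = rep(1, n_keep), tau_gamma = rep(1, n_keep),
         tau_a = rep(1, n_keep),
         accept = list(theta = 0.4, gamma = rep(0.4, ncol(gamma)), a = 0.4))
  }
  structure(
    list(chains = lapply(seq_len(chains), function(i) one()),
         node_ids = colnames(a),
         covariate_names = colnames(gamma),
         config = sampler_config(burn_in = 0, draws = n_keep, thin = 1,
                                 chains = chains, seed = 1),
         seeds = seq_len(chains)),
    class = "p2_samples"
  )
}

# brute-force O(n^3) agglomerative complete linkage: returns the sequence
# of merge heights and the partition after stopping at k clusters
bf_complete_linkage <- function(D, k = 1L) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  labels_at_k <- NULL
  snapshot <- function() {
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    lab
  }
  if (length(clusters) == k) labels_at_k <- snapshot()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- j; bj <- i }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    if (length(clusters) == k) labels_at_k <- snapshot()
  }
  list(heights = heights, labels = labels_at_k)
}

# canonical form of a partition (label vectors comparable across methods)
partition_id <- function(labels) {
  match(labels, unique(labels))
}

# brute-force per-pair Bernoulli log-likelihood used as the model oracle
bf_log_likelihood <- function(net, theta, alpha) {
  nodes <- net$nodes
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    adj[net$edges] <- 1L
    adj[net$edges[, 2:1, drop = FALSE]] <- 1L
  }
  ll <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_len(i - 1L)) {
      p <- 1 / (1 + exp(-(theta + alpha[i] + alpha[j])))
      ll <- ll + if (adj[i, j]) log(p) else log(1 - p)
    }
  }
  ll
}

# one small well-identified fit with a covariate, shared across tests
# (memoized: several blocks diagnose or summarize the same chains)
cached_fit_env <- new.env()
small_covariate_fit <- function() {
  if (!is.null(cached_fit_env$fit)) return(cached_fit_env$fit)
  study <- generate_synthetic_study(n = 60, theta = -2, gamma = 1,
                                    sigma_a = 0.8, prevalence = 0.3,
                                    seed = 404)
  cfg <- sampler_config(burn_in = 1000, draws = 4000, thin = 5,
                        chains = 2, seed = 11)
  fit <- run_chains(study$network, study$covariates, config = cfg)
  cached_fit_env$fit <- list(study = study, samples = fit)
  cached_fit_env$fit
}
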