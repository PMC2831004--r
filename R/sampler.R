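#' Sampler configuration
#'
#' Iteration counts default to the full analysis profile (50000 burn-in,
#' 100000 estimation iterations, thinning 10, two parallel chains); the
#' `"desk"` profile (2000/8000) is a scaled-down setting for interactive
#' use and simulation studies. Chain seeds are derived deterministically
#' from `seed`, so identical configuration, seed and data give
#' bit-identical output.
#'
#' @param burn_in iterations discarded before estimation.
#' @param draws estimation iterations (before thinning).
#' @param thin keep every `thin`-th draw.
#' @param chains number of parallel chains.
#' @param seed integer master seed.
#' @param scales initial random-walk proposal standard deviations for the
#'   `theta`, `gamma` and `a` blocks.
#' @param adapt adapt proposal scales toward 0.44 acceptance during
#'   burn-in only (frozen afterwards, preserving the stationary law).
#' @param profile optional shortcut: `"paper"` sets 50000/100000,
#'   `"desk"` sets 2000/8000, overriding `burn_in`/`draws`.
#' @return an object of class `p2_config`.
#' @export
sampler_config <- function(burn_in = 50000, draws = 100000, thin = 10,
                           chains = 2, seed = 1,
                           scales = c(theta = 0.2, gamma = 0.2, a = 0.8),
                           adapt = TRUE, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("paper", "desk"))
    if (profile == "paper") {
      burn_in <- 50000; draws <- 100000
    } else {
      burn_in <- 2000; draws <- 8000
    }
  }
  stopifnot(burn_in >= 0, draws >= 1, thin >= 1, chains >= 1,
            all(scales > 0))
  structure(
    list(burn_in = as.integer(burn_in), draws = as.integer(draws),
         thin = as.integer(thin), chains = as.integer(chains),
         seed = as.integer(seed),
         scales = c(theta = unname(scales[["theta"]]),
                    gamma = unname(scales[["gamma"]]),
                    a = unname(scales[["a"]])),
         adapt = isTRUE(adapt), profile = profile),
    class = "p2_config"
  )
}

#' Conjugate update of a normal precision
#'
#' Given zero-mean normal observations `values` with precision tau and a
#' Gamma(a0, b0) prior on tau, the full conditional is
#' Gamma(a0 + k/2, b0 + sum(values^2)/2); this draws once from it. An
#' empty `values` vector returns a draw from the prior.
#'
#' @param values numeric vector of current zero-mean normal variates.
#' @param hyper a [p2_hyper()].
#' @return one positive draw of the precision.
#' @export
update_precision <- function(values, hyper = p2_hyper()) {
  stopifnot(all(is.finite(values)))
  stats::rgamma(1L, shape = hyper$a0 + length(values) / 2,
                rate = hyper$b0 + sum(values^2) / 2)
}

#' One random-walk Metropolis step
#'
#' Symmetric normal proposal around the current value; accepted with
#' probability `min(1, exp(delta log target))`.
#'
#' @param current current value (scalar or vector).
#' @param log_target function returning the log target density.
#' @param scale proposal standard deviation, > 0.
#' @return list with `value` (new state) and `accepted` flag.
#' @export
metropolis_block <- function(current, log_target, scale) {
  stopifnot(scale > 0)
  lt_cur <- log_target(current)
  if (!is.finite(lt_cur)) stop("log target is not finite at current value")
  prop <- current + stats::rnorm(length(current), 0, scale)
  lt_prop <- log_target(prop)
  if (is.finite(lt_prop) && log(stats::runif(1L)) < lt_prop - lt_cur) {
    list(value = prop, accepted = TRUE)
  } else {
    list(value = current, accepted = FALSE)
  }
}

default_init <- function(net) {
  n <- length(net$nodes)
  dens <- nrow(net$edges) / (n * (n - 1) / 2)
  dens <- min(max(dens, 1 / (n * n)), 1 - 1 / (n * n))
  list(theta = stats::qlogis(dens), gamma = NULL, a = rep(0, n),
       tau_theta = 1, tau_gamma = 1, tau_a = 1)
}

#' Run one MCMC chain
#'
#' A Metropolis-within-Gibbs sweep updates `theta`, each covariate effect
#' and each node random effect by adaptive random-walk Metropolis (the
#' random-effect conditional touches only that node's incident dyads), and
#' the three precisions by exact conjugate gamma draws. Burn-in draws are
#' discarded and the retained draws thinned.
#'
#' @param net undirected `p2_network` with at least 2 nodes.
#' @param covariates aligned covariate table or `NULL`.
#' @param hyper a [p2_hyper()].
#' @param config a [sampler_config()].
#' @param chain_seed integer seed for this chain's RNG stream.
#' @param init optional named list overriding initial values (`theta`,
#'   `gamma`, `a`, `tau_theta`, `tau_gamma`, `tau_a`); defaults are
#'   `theta` = logit of the observed density, `gamma` = 0, `a` = 0,
#'   precisions 1.
#' @return list of draw vectors/matrices (`theta`, `gamma`, `a`,
#'   `tau_theta`, `tau_gamma`, `tau_a`), acceptance rates, final scales
#'   and the seed used.
#' @export
run_chain <- function(net, covariates = NULL, hyper = p2_hyper(),
                      config = sampler_config(), chain_seed = config$seed,
                      init = NULL) {
  if (net$directed) stop("the sampler fits undirected networks")
  n <- length(net$nodes)
  if (n < 2L) stop("need at least 2 nodes")
  if (config$draws < 1L) stop("draws must be >= 1")
  covariates <- align_covariates(net, covariates)
  X <- covariate_matrix(covariates, n)
  m <- ncol(X)
  ini <- default_init(net)
  ini$gamma <- rep(0, m)
  if (!is.null(init)) ini[names(init)] <- init
  if (length(ini$gamma) != m) stop("init$gamma has wrong length")
  if (length(ini$a) != n) stop("init$a has wrong length")
  adj <- adjacency_matrix(net)
  set.seed(chain_seed)
  res <- .p2_chain_cpp(adj, X, hyper$a0, hyper$b0,
                       config$burn_in, config$draws, config$thin,
                       ini$theta, ini$gamma, ini$a,
                       ini$tau_theta, ini$tau_gamma, ini$tau_a,
                       config$scales[["theta"]], config$scales[["gamma"]],
                       config$scales[["a"]], config$adapt)
  colnames(res$a) <- net$nodes
  if (m > 0L) colnames(res$gamma) <- colnames(X)
  res$seed <- chain_seed
  res
}

#' Run parallel chains from overdispersed starting points
#'
#' Chains get distinct seeds derived from the master seed; chain c starts
#' from `theta` alternating between -4 and 0, `a_i ~ Normal(0, 1)` drawn
#' from the chain's own stream, `gamma = 0` and unit precisions, so that
#' agreement between chains is informative about convergence.
#'
#' @inheritParams run_chain
#' @return an object of class `p2_samples`: per-chain draws plus node
#'   IDs, covariate names, configuration and seeds.
#' @export
run_chains <- function(net, covariates = NULL, hyper = p2_hyper(),
                       config = sampler_config()) {
  if (config$chains < 1L) stop("chains must be >= 1")
  covariates <- align_covariates(net, covariates)
  n <- length(net$nodes)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$chains)
  chains <- vector("list", config$chains)
  for (c in seq_len(config$chains)) {
    set.seed(seeds[c])
    init <- list(theta = c(-4, 0)[(c - 1L) %% 2L + 1L],
                 a = stats::rnorm(n))
    chains[[c]] <- run_chain(net, covariates, hyper, config,
                             chain_seed = seeds[c], init = init)
  }
  structure(
    list(chains = chains, node_ids = net$nodes,
         covariate_names = colnames(covariate_matrix(covariates, n)),
         config = config, seeds = seeds),
    class = "p2_samples"
  )
}

#' @export
print.p2_samples <- function(x, ...) {
  cat(sprintf(
    "p2_samples: %d chain(s) x %d retained draws, %d nodes, %d covariate(s)\n",
    length(x$chains), length(x$chains[[1L]]$theta), length(x$node_ids),
    length(x$covariate_names)))
  cat(sprintf("  burn-in %d, draws %d, thin %d, master seed %d\n",
              x$config$burn_in, x$config$draws, x$config$thin,
              x$config$seed))
  invisible(x)
}

# pooled draw matrix for one scalar parameter across chains
pooled_draws <- function(samples, extract) {
  unlist(lapply(samples$chains, extract), use.names = FALSE)
}

#' Per-chain draw vectors of a scalar parameter
#'
#' @param samples a `p2_samples` object.
#' @param param `"theta"`, `"tau_theta"`, `"tau_gamma"`, `"tau_a"`, a
#'   covariate name, or a node ID.
#' @return list of numeric draw vectors, one per chain.
#' @export
chain_draws <- function(samples, param) {
  lapply(samples$chains, function(ch) {
    switch(param,
           theta = ch$theta,
           tau_theta = ch$tau_theta,
           tau_gamma = ch$tau_gamma,
           tau_a = ch$tau_a,
           {
             if (param %in% colnames(ch$gamma)) ch$gamma[, param]
             else if (param %in% colnames(ch$a)) ch$a[, param]
             else stop("unknown parameter '", param, "'")
           })
  })
}
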