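#' Model parameters for the undirected p2 model
#'
#' Bundles the global density parameter `theta`, covariate effects
#' `gamma` (length m, possibly empty), node random effects `a` (length
#' n), and the three precisions `tau_theta`, `tau_gamma`, `tau_a`
#' (inverse variances of the corresponding zero-mean normal priors).
#' Node socialities derive as `alpha_i = gamma . x_i + a_i`.
#'
#' @param theta global density (log-odds of an edge between two nodes
#'   with zero sociality).
#' @param gamma numeric vector of covariate effects on sociality.
#' @param a numeric vector of node random effects, one per node.
#' @param tau_theta,tau_gamma,tau_a strictly positive precisions.
#' @return an object of class `p2_params`.
#' @export
p2_params <- function(theta, gamma = numeric(0), a,
                      tau_theta = 1, tau_gamma = 1, tau_a = 1) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(gamma), is.numeric(a), all(is.finite(a)))
  taus <- c(tau_theta = tau_theta, tau_gamma = tau_gamma, tau_a = tau_a)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("precisions must be strictly positive")
  }
  structure(
    list(theta = theta, gamma = as.numeric(gamma), a = as.numeric(a),
         tau_theta = tau_theta, tau_gamma = tau_gamma, tau_a = tau_a),
    class = "p2_params"
  )
}

#' Hyperparameters of the gamma priors on precisions
#'
#' All precisions receive a conjugate Gamma(a0, b0) prior; the default
#' a0 = b0 = 0.001 makes the implied priors on the standard deviations
#' effectively noninformative.
#'
#' @param a0 shape, > 0.
#' @param b0 rate, > 0.
#' @return an object of class `p2_hyper`.
#' @export
p2_hyper <- function(a0 = 0.001, b0 = 0.001) {
  stopifnot(is.numeric(a0), is.numeric(b0), a0 > 0, b0 > 0)
  structure(list(a0 = a0, b0 = b0), class = "p2_hyper")
}

#' Node socialities implied by parameters and covariates
#'
#' `alpha_i = gamma . x_i + a_i`: the covariate regression plus the
#' node's random effect.
#'
#' @param params a [p2_params()].
#' @param covariates aligned covariate table (or `NULL` when the model
#'   has no covariates).
#' @return numeric vector of socialities, one per node.
#' @export
sociality <- function(params, covariates = NULL) {
  X <- covariate_matrix(covariates, length(params$a))
  if (ncol(X) != length(params$gamma)) {
    stop("covariate count (", ncol(X), ") does not match gamma length (",
         length(params$gamma), ")")
  }
  unname(drop(X %*% params$gamma)) + params$a
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    return(matrix(0, n, 0L))
  }
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (nrow(X) != n) {
    stop("covariate table has ", nrow(X), " rows for ", n, " nodes")
  }
  X
}

#' Edge probability under the undirected p2 model
#'
#' The probability that nodes i and j are connected is the inverse logit
#' of `theta + alpha_i + alpha_j`; it is symmetric in the two socialities
#' and saturates smoothly at extreme inputs.
#'
#' @param theta global density parameter.
#' @param alpha_i,alpha_j socialities of the two endpoints.
#' @return probability in (0, 1).
#' @export
edge_probability <- function(theta, alpha_i, alpha_j) {
  # alpha sum grouped first so the value is bitwise symmetric in (i, j)
  stats::plogis(theta + (alpha_i + alpha_j))
}

#' Log-likelihood of an undirected network
#'
#' Sum over unordered node pairs i < j of the Bernoulli log-probability
#' of the observed edge indicator with success probability
#' `edge_probability(theta, alpha_i, alpha_j)`. Computed in log space
#' throughout, so it is finite for any finite parameters.
#'
#' @param net an undirected `p2_network`.
#' @param params a [p2_params()] with one random effect per node.
#' @param covariates aligned covariates (or `NULL`).
#' @return the log-likelihood.
#' @export
log_likelihood <- function(net, params, covariates = NULL) {
  if (net$directed) {
    stop("log_likelihood is for undirected networks; use ",
         "dyad_probabilities_directed for directed dyads")
  }
  n <- length(net$nodes)
  if (length(params$a) != n) {
    stop("params$a has length ", length(params$a), " for ", n, " nodes")
  }
  alpha <- sociality(params, covariates)
  eta <- params$theta + outer(alpha, alpha, `+`)
  x <- adjacency_matrix(net)
  up <- upper.tri(eta)
  # log p and log(1-p) via plogis(log.p=) for numerical stability
  lp <- stats::plogis(eta[up], log.p = TRUE)
  lq <- stats::plogis(-eta[up], log.p = TRUE)
  sum(x[up] * lp + (1 - x[up]) * lq)
}

#' Log prior density of the model parameters
#'
#' theta ~ Normal(0, tau_theta^-1); each gamma component ~
#' Normal(0, tau_gamma^-1); each a_i ~ Normal(0, tau_a^-1); each
#' precision ~ Gamma(a0, b0). All terms on the log scale.
#'
#' @param params a [p2_params()].
#' @param hyper a [p2_hyper()].
#' @return the log prior density.
#' @export
log_prior <- function(params, hyper = p2_hyper()) {
  taus <- c(params$tau_theta, params$tau_gamma, params$tau_a)
  if (any(taus <= 0)) stop("precisions must be strictly positive")
  lp <- stats::dnorm(params$theta, 0, 1 / sqrt(params$tau_theta), log = TRUE) +
    stats::dgamma(params$tau_theta, hyper$a0, rate = hyper$b0, log = TRUE) +
    stats::dgamma(params$tau_gamma, hyper$a0, rate = hyper$b0, log = TRUE) +
    stats::dgamma(params$tau_a, hyper$a0, rate = hyper$b0, log = TRUE) +
    sum(stats::dnorm(params$gamma, 0, 1 / sqrt(params$tau_gamma), log = TRUE)) +
    sum(stats::dnorm(params$a, 0, 1 / sqrt(params$tau_a), log = TRUE))
  lp
}

#' Log posterior (unnormalized) of the model
#'
#' @inheritParams log_likelihood
#' @param hyper a [p2_hyper()].
#' @return `log_likelihood + log_prior`.
#' @export
log_posterior <- function(net, params, covariates = NULL,
                          hyper = p2_hyper()) {
  log_likelihood(net, params, covariates) + log_prior(params, hyper)
}

#' Directed p1 dyad probabilities
#'
#' For a directed pair (i, j) the dyad takes one of four states: null,
#' edge i->j only, edge j->i only, or mutual. Their probabilities come
#' from the log-linear p1 equations with density `theta`, reciprocity
#' `phi`, expansiveness `alpha` and attractiveness `beta`; the scaling
#' constant (the log of the null probability, the "residual") normalizes
#' the four cells to sum to one.
#'
#' @param theta density parameter.
#' @param phi reciprocity parameter.
#' @param alpha_i,beta_i expansiveness/attractiveness of node i.
#' @param alpha_j,beta_j expansiveness/attractiveness of node j.
#' @return list with probabilities `m` (mutual), `a_ij` (i->j only),
#'   `a_ji` (j->i only), `n` (null), and `lambda` (log of `n`).
#' @export
dyad_probabilities_directed <- function(theta, phi, alpha_i, beta_i,
                                        alpha_j, beta_j) {
  lw <- c(
    n    = 0,
    a_ij = theta + alpha_i + beta_j,
    a_ji = theta + alpha_j + beta_i,
    m    = 2 * theta + alpha_i + alpha_j + beta_i + beta_j + phi
  )
  mx <- max(lw)
  w <- exp(lw - mx)
  p <- w / sum(w)
  list(m = unname(p["m"]), a_ij = unname(p["a_ij"]),
       a_ji = unname(p["a_ji"]), n = unname(p["n"]),
       lambda = unname(log(p["n"])))
}
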