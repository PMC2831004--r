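test_that("sociality is the covariate regression plus the random effect", {
  p <- p2_params(theta = 0, gamma = 0.06, a = 0.5)
  cov <- data.frame(g = 1, row.names = "A")
  expect_equal(sociality(p, cov), 0.56, ignore_attr = TRUE)

  p0 <- p2_params(theta = 0, gamma = numeric(0), a = c(0.3, -0.2))
  expect_equal(sociality(p0), c(0.3, -0.2))

  # two covariates: matches an independent dot product
  set.seed(5)
  X <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], c("u", "v")))
  g <- rnorm(2); a <- rnorm(4)
  p2 <- p2_params(theta = 0, gamma = g, a = a)
  expect_equal(sociality(p2, as.data.frame(X)),
               as.numeric(X %*% g) + a)

  expect_error(sociality(p2, as.data.frame(X[, 1, drop = FALSE])),
               "does not match gamma length")
})

test_that("edge probability is the symmetric inverse logit of the sum", {
  expect_equal(signif(edge_probability(-5.68, 0, 0), 2), 0.0034)
  expect_equal(edge_probability(0, 0, 0), 0.5)
  # two high-sociality nodes: 1 / (1 + exp(-(-5.68 + 3.48 + 3.41)))
  expect_equal(edge_probability(-5.68, 3.48, 3.41), 1 / (1 + exp(-1.21)),
               tolerance = 1e-10)
  expect_equal(round(edge_probability(-5.68, 3.48, 3.41), 4), 0.7703)
  set.seed(1)
  for (i in 1:20) {
    th <- rnorm(1); ai <- rnorm(1); aj <- rnorm(1)
    expect_identical(edge_probability(th, ai, aj),
                     edge_probability(th, aj, ai))
  }
  # saturates without NaN
  expect_equal(edge_probability(1000, 0, 0), 1)
  expect_equal(edge_probability(-1000, 0, 0), 0)
})

test_that("log-likelihood matches the per-pair Bernoulli product", {
  empty <- p2_network(c("A", "B", "C"), NULL)
  p <- p2_params(theta = 0, a = rep(0, 3))
  expect_equal(log_likelihood(empty, p), 3 * log(0.5))
  expect_equal(log_likelihood(triangle_network(), p), 3 * log(0.5))

  set.seed(9)
  for (rep in 1:10) {
    alpha <- rnorm(4)
    th <- rnorm(1)
    net <- simulate_network(0, rep(0, 4), LETTERS[1:4])
    pp <- p2_params(theta = th, a = alpha)
    expect_equal(log_likelihood(net, pp), bf_log_likelihood(net, th, alpha),
                 tolerance = 1e-12)
  }

  dir_net <- p2_network(c("A", "B"), rbind(c("A", "B")), directed = TRUE)
  expect_error(log_likelihood(dir_net, p2_params(theta = 0, a = c(0, 0))),
               "undirected")
})

test_that("the dyad-independent likelihood is normalized over graph space", {
  # sum over all 2^6 undirected graphs on 4 nodes must be 1
  pairs <- t(combn(LETTERS[1:4], 2))
  set.seed(31)
  for (rep in 1:3) {
    th <- rnorm(1)
    alpha <- rnorm(4)
    total <- 0
    for (code in 0:63) {
      on <- as.logical(bitwAnd(code, 2^(0:5)))
      net <- p2_network(LETTERS[1:4], pairs[on, , drop = FALSE])
      total <- total + exp(log_likelihood(net, p2_params(theta = th, a = alpha)))
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("with zero socialities the model reduces to Erdos-Renyi", {
  set.seed(12)
  th <- -1.3
  p <- plogis(th)
  net <- simulate_network(th, rep(0, 10))
  e <- n_edges(net)
  n_pairs <- choose(10, 2)
  expect_equal(log_likelihood(net, p2_params(theta = th, a = rep(0, 10))),
               e * log(p) + (n_pairs - e) * log(1 - p))
})

test_that("log prior sums the normal and gamma terms", {
  hy <- p2_hyper()
  # theta = 0 is the mode of its zero-mean normal term at fixed tau
  base <- p2_params(theta = 0, gamma = 0.1, a = c(0.2, -0.1))
  for (th in c(-1, -0.1, 0.1, 1)) {
    shifted <- p2_params(theta = th, gamma = 0.1, a = c(0.2, -0.1))
    expect_lt(log_prior(shifted, hy), log_prior(base, hy))
  }
  # term-by-term independent recomputation
  set.seed(4)
  p <- p2_params(theta = rnorm(1), gamma = rnorm(2), a = rnorm(5),
                 tau_theta = rgamma(1, 2), tau_gamma = rgamma(1, 2),
                 tau_a = rgamma(1, 2))
  manual <- dnorm(p$theta, 0, p$tau_theta^-0.5, log = TRUE) +
    sum(dnorm(p$gamma, 0, p$tau_gamma^-0.5, log = TRUE)) +
    sum(dnorm(p$a, 0, p$tau_a^-0.5, log = TRUE)) +
    sum(dgamma(c(p$tau_theta, p$tau_gamma, p$tau_a),
               hy$a0, rate = hy$b0, log = TRUE))
  expect_equal(log_prior(p, hy), manual, tolerance = 1e-12)

  expect_error(p2_params(theta = 0, a = 0:1, tau_a = 0), "positive")
})

test_that("log posterior is likelihood plus prior and respects symmetry", {
  set.seed(21)
  net <- simulate_network(-0.5, rnorm(6), letters[1:6])
  p <- p2_params(theta = -0.5, a = rnorm(6))
  expect_equal(log_posterior(net, p),
               log_likelihood(net, p) + log_prior(p))

  # pushing up the sociality of a node with no absent... with absent edges
  # lowers the posterior eventually
  deg <- degree_sequence(net)
  i <- which(deg < 5)[1L]  # node with at least one absent edge
  vals <- vapply(c(0, 2, 5, 10, 20), function(s) {
    a2 <- p$a; a2[i] <- a2[i] + s
    log_posterior(net, p2_params(theta = p$theta, a = a2))
  }, numeric(1))
  expect_true(all(diff(vals[3:5]) < 0))

  # invariance under node relabeling with permuted random effects
  perm <- sample(6)
  net_p <- p2_network(net$nodes[perm],
                      net$edges)
  p_perm <- p2_params(theta = p$theta, a = p$a[perm])
  expect_equal(log_posterior(net_p, p_perm), log_posterior(net, p),
               tolerance = 1e-12)
})

test_that("directed dyad probabilities normalize and match hand values", {
  flat <- dyad_probabilities_directed(0, 0, 0, 0, 0, 0)
  expect_equal(unlist(flat[c("m", "a_ij", "a_ji", "n")]),
               c(m = 0.25, a_ij = 0.25, a_ji = 0.25, n = 0.25))

  set.seed(8)
  for (rep in 1:20) {
    v <- rnorm(6)
    d <- dyad_probabilities_directed(v[1], v[2], v[3], v[4], v[5], v[6])
    expect_equal(d$m + d$a_ij + d$a_ji + d$n, 1, tolerance = 1e-12)
    expect_true(all(unlist(d[c("m", "a_ij", "a_ji", "n")]) >= 0))
  }

  # theta = 1, phi = 2, alpha = beta = 0: masses (e^4, e, e, 1)
  d <- dyad_probabilities_directed(1, 2, 0, 0, 0, 0)
  z <- exp(4) + exp(1) + exp(1) + 1
  expect_equal(d$m, exp(4) / z, tolerance = 1e-12)
  expect_equal(d$a_ij, exp(1) / z, tolerance = 1e-12)
  expect_equal(d$n, 1 / z, tolerance = 1e-12)
  expect_equal(d$lambda, log(1 / z), tolerance = 1e-12)
})

test_that("with zero reciprocity the dyad factorizes into two edges", {
  # phi = 0: P(X_ij = 1) marginal must equal expit(theta + alpha_i + beta_j)
  th <- 0.7; ai <- 0.3; bi <- -0.2; aj <- -0.5; bj <- 0.9
  d <- dyad_probabilities_directed(th, 0, ai, bi, aj, bj)
  p_ij <- d$m + d$a_ij
  p_ji <- d$m + d$a_ji
  expect_equal(p_ij, plogis(th + ai + bj), tolerance = 1e-12)
  expect_equal(p_ji, plogis(th + aj + bi), tolerance = 1e-12)
  # and the two edges are independent
  expect_equal(d$m, p_ij * p_ji, tolerance = 1e-12)
})
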