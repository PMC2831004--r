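#' Summarize a fitted p2 model
#'
#' Pools chains (after a convergence gate: PSRF of the global parameters
#' must be below 1.1 unless `force = TRUE`), reconstructs each node's
#' sociality per draw as `alpha_i = gamma . x_i + a_i`, and reports the
#' posterior mean, standard deviation and central 95% quantiles of alpha
#' for every node, together with its degree and covariates, sorted by
#' posterior mean sociality in decreasing order. Global summaries of
#' `theta` and each covariate effect are included.
#'
#' Quantiles use linear interpolation between order statistics (the
#' standard type-7 default).
#'
#' @param samples a `p2_samples` object.
#' @param net the fitted `p2_network`.
#' @param covariates the aligned covariate table used in the fit (or
#'   `NULL`).
#' @param force pool chains even if the PSRF gate fails.
#' @return an object of class `p2_fit_summary`: `nodes` (per-node table),
#'   `global` (theta and gamma rows), plus alpha draw matrix kept for
#'   downstream checks.
#' @export
summarize_fit <- function(samples, net, covariates = NULL, force = FALSE) {
  covariates <- align_covariates(net, covariates)
  n <- length(net$nodes)
  X <- covariate_matrix(covariates, n)
  if (length(samples$chains) >= 2L && !force) {
    gate_pars <- c("theta", samples$covariate_names)
    psrf <- vapply(gate_pars, function(p) {
      tryCatch(gelman_rubin(chain_draws(samples, p)),
               error = function(e) NA_real_)
    }, numeric(1))
    bad <- gate_pars[!is.na(psrf) & psrf >= 1.1]
    if (length(bad)) {
      stop("convergence gate: PSRF >= 1.1 for ",
           paste(bad, collapse = ", "),
           " (use force = TRUE to pool anyway)")
    }
  }
  alpha <- do.call(rbind, lapply(samples$chains, function(ch) {
    ad <- ch$a
    if (ncol(X) > 0L) ad <- ad + ch$gamma %*% t(X)
    ad
  }))
  colnames(alpha) <- net$nodes
  q <- apply(alpha, 2L, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE)
  deg <- degree_sequence(net)
  nodes <- data.frame(
    id = net$nodes,
    degree = as.integer(deg[net$nodes]),
    alpha_mean = colMeans(alpha),
    alpha_sd = apply(alpha, 2L, stats::sd),
    q2.5 = q[1L, ],
    q97.5 = q[2L, ],
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if (ncol(X) > 0L) nodes <- cbind(nodes, as.data.frame(X))
  nodes$positive_mean <- nodes$alpha_mean > 0
  nodes$social <- nodes$q2.5 > 0
  nodes <- nodes[order(-nodes$alpha_mean), , drop = FALSE]
  rownames(nodes) <- NULL

  glob_row <- function(name, draws) {
    qq <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = name, mean = mean(draws),
               sd = stats::sd(draws), q2.5 = qq[1L], q97.5 = qq[2L],
               stringsAsFactors = FALSE)
  }
  global <- glob_row("theta", pooled_draws(samples, function(ch) ch$theta))
  for (cn in samples$covariate_names) {
    global <- rbind(global,
                    glob_row(cn, pooled_draws(samples,
                                              function(ch) ch$gamma[, cn])))
  }
  structure(
    list(nodes = nodes, global = global, alpha_draws = alpha,
         n_chains = length(samples$chains)),
    class = "p2_fit_summary"
  )
}

#' @export
print.p2_fit_summary <- function(x, ...) {
  th <- x$global[x$global$parameter == "theta", ]
  cat(sprintf("p2 fit: theta = %.2f (%.2f); %d nodes, %d social\n",
              th$mean, th$sd, nrow(x$nodes), sum(x$nodes$social)))
  print(utils::head(x$nodes[, setdiff(names(x$nodes), "positive_mean")],
                    10L), digits = 3)
  invisible(x)
}

#' Call social nodes from a fit summary
#'
#' A node is *social* when the 2.5% posterior quantile of its sociality
#' alpha is strictly greater than zero — its positive contribution to
#' edge formation is credible, not just its point estimate. The count of
#' nodes with merely positive posterior mean is reported alongside.
#'
#' @param summary a `p2_fit_summary`.
#' @return list with `social` (node IDs sorted by decreasing mean alpha)
#'   and `n_positive_mean`.
#' @export
call_social <- function(summary) {
  nodes <- summary$nodes
  list(social = nodes$id[nodes$social],
       n_positive_mean = sum(nodes$positive_mean))
}

#' Report a covariate effect on sociality
#'
#' Returns the posterior mean, sd and central 95% interval of the named
#' effect together with a plain-language verdict: the effect is
#' "credible" when the 95% interval excludes zero.
#'
#' @param summary a `p2_fit_summary`.
#' @param which covariate name.
#' @return list with `covariate`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `verdict`.
#' @export
covariate_effect <- function(summary, which) {
  g <- summary$global[summary$global$parameter == which, ]
  if (nrow(g) != 1L) stop("unknown covariate '", which, "'")
  verdict <- if (g$mean == 0 && g$sd == 0) {
    "no effect"
  } else if (g$mean > 0) {
    if (g$q2.5 > 0) "positive effect, credible"
    else "positive effect, not credible"
  } else {
    if (g$q97.5 < 0) "negative effect, credible"
    else "negative effect, not credible"
  }
  list(covariate = which, mean = g$mean, sd = g$sd,
       q2.5 = g$q2.5, q97.5 = g$q97.5, verdict = verdict)
}

#' Write a fit summary to CSV
#'
#' Column order: id, degree, alpha_mean, alpha_sd, q2.5, q97.5,
#' covariates..., positive_mean, social.
#'
#' @param summary a `p2_fit_summary`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(summary, path) {
  utils::write.csv(summary$nodes, path, row.names = FALSE)
  invisible(path)
}
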