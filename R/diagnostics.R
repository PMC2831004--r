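# Spectral density at frequency zero of a (possibly autocorrelated)
# chain, via the fitted-AR(p) estimator: s(0) = sigma^2 / (1 - sum(phi))^2.
spectrum0 <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) stop("degenerate chain: zero variance")
  fit <- stats::ar(x, aic = TRUE, order.max = min(30L, length(x) - 1L))
  if (length(fit$ar) == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of the chain with the mean of a
#' late window; under convergence the standardized difference is
#' approximately standard normal. Window variances are estimated by the
#' spectral density at frequency zero (AR-fit estimator), so
#' autocorrelation within each window is accounted for.
#'
#' @param chain numeric draw vector, length >= 100.
#' @param first fraction of the chain in the early window (default 0.1).
#' @param last fraction in the late window (default 0.5).
#' @return the z score.
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  n <- length(chain)
  if (n < 100L) stop("chain too short for the Geweke diagnostic (< 100)")
  if (first <= 0 || last <= 0 || first + last > 1) {
    stop("window fractions must be positive with first + last <= 1")
  }
  x1 <- chain[seq_len(floor(first * n))]
  x2 <- chain[seq.int(n - floor(last * n) + 1L, n)]
  s1 <- spectrum0(x1) / length(x1)
  s2 <- spectrum0(x2) / length(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 + s2)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance construction: with m chains
#' of length n, `W` is the mean within-chain variance, `B/n` the variance
#' of the chain means, and the PSRF is `sqrt(((n-1)/n W + B/n) / W)`.
#' Values near 1 indicate that the chains are sampling the same
#' distribution; > 1.1 is the customary trouble flag.
#'
#' @param chains list of >= 2 equal-length numeric draw vectors.
#' @return the PSRF.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L) {
    stop("Gelman-Rubin needs >= 2 chains")
  }
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 10L) stop("chains too short (< 10)")
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B_over_n <- stats::var(means)
  if (W == 0) stop("degenerate chains: zero within-chain variance")
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Convergence report for a posterior sample set
#'
#' Computes the Geweke z score per chain and the Gelman-Rubin PSRF across
#' chains for the global parameters (`theta`, each covariate effect, the
#' three precisions) and optionally every node random effect. Flags mark
#' |z| > 1.96 and PSRF > 1.1.
#'
#' @param samples a `p2_samples` object.
#' @param include_nodes also diagnose each `a_i` (default `FALSE`).
#' @return data frame of class `p2_diagnostics` with columns `parameter`,
#'   `chain`, `geweke_z`, `psrf`, `geweke_flag`, `psrf_flag`. The PSRF is
#'   repeated across the chain rows of a parameter; it is `NA` for
#'   single-chain runs.
#' @export
diagnostic_report <- function(samples, include_nodes = FALSE) {
  pars <- c("theta", samples$covariate_names,
            "tau_theta", "tau_gamma", "tau_a")
  if (include_nodes) pars <- c(pars, samples$node_ids)
  rows <- lapply(pars, function(p) {
    ch <- chain_draws(samples, p)
    z <- vapply(ch, function(v) {
      tryCatch(geweke_z(v), error = function(e) NA_real_)
    }, numeric(1))
    psrf <- if (length(ch) >= 2L) {
      tryCatch(gelman_rubin(ch), error = function(e) NA_real_)
    } else NA_real_
    data.frame(parameter = p, chain = seq_along(ch), geweke_z = z,
               psrf = psrf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$geweke_flag <- !is.na(out$geweke_z) & abs(out$geweke_z) > 1.96
  out$psrf_flag <- !is.na(out$psrf) & out$psrf > 1.1
  class(out) <- c("p2_diagnostics", "data.frame")
  out
}

#' Write a diagnostic report to CSV
#' @param report a `p2_diagnostics` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
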