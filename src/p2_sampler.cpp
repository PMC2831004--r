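#include <Rcpp.h>
using namespace Rcpp;

// log(expit(z)) without overflow at either tail
static inline double log_expit(double z) {
  return (z < 0.0) ? z - log1p(exp(z)) : -log1p(exp(-z));
}

static double full_loglik(const IntegerMatrix &adj, double theta,
                          const NumericVector &alpha) {
  const int n = alpha.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double eta = theta + alpha[i] + alpha[j];
      ll += adj(i, j) ? log_expit(eta) : log_expit(-eta);
    }
  }
  return ll;
}

// likelihood terms incident to node i, with its sociality set to alpha_i
static double node_loglik(const IntegerMatrix &adj, double theta,
                          const NumericVector &alpha, int i, double alpha_i) {
  const int n = alpha.size();
  double ll = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double eta = theta + alpha_i + alpha[j];
    ll += adj(i, j) ? log_expit(eta) : log_expit(-eta);
  }
  return ll;
}

static inline double rgamma_rate(double shape, double rate) {
  return R::rgamma(shape, 1.0 / rate);
}

// Metropolis-within-Gibbs sweep sampler for the undirected p2 model.
// Location blocks (theta, each gamma_k, each a_i) use random-walk
// Metropolis with per-block scales adapted toward 0.44 acceptance during
// burn-in only; precisions use exact conjugate gamma draws. Uses R's RNG
// stream, so reproducibility is governed by set.seed() in the caller.
// [[Rcpp::export(name = ".p2_chain_cpp")]]
List p2_chain_cpp(IntegerMatrix adj, NumericMatrix X,
                  double a0, double b0,
                  int burn_in, int draws, int thin,
                  double theta_init, NumericVector gamma_init,
                  NumericVector a_init,
                  double tau_theta_init, double tau_gamma_init,
                  double tau_a_init,
                  double scale_theta, double scale_gamma, double scale_a,
                  bool adapt) {
  const int n = adj.nrow();
  const int m = X.ncol();
  if (n < 2) stop("need at least 2 nodes");
  if (draws < 1) stop("draws must be >= 1");
  if (thin < 1) stop("thin must be >= 1");

  double theta = theta_init;
  NumericVector gamma = clone(gamma_init);
  NumericVector a = clone(a_init);
  double tau_theta = tau_theta_init;
  double tau_gamma = tau_gamma_init;
  double tau_a = tau_a_init;

  NumericVector alpha(n);
  for (int i = 0; i < n; ++i) {
    double s = a[i];
    for (int k = 0; k < m; ++k) s += X(i, k) * gamma[k];
    alpha[i] = s;
  }

  double ls_theta = log(scale_theta);
  NumericVector ls_gamma(m, log(scale_gamma));
  double ls_a = log(scale_a);

  const int n_keep = draws / thin;
  NumericVector out_theta(n_keep), out_tau_theta(n_keep),
      out_tau_gamma(n_keep), out_tau_a(n_keep);
  NumericMatrix out_gamma(n_keep, m), out_a(n_keep, n);

  // acceptance bookkeeping: batch counters for adaptation, run counters
  // (post burn-in) for reporting
  const int batch = 50;
  int bt_theta = 0, bt_a = 0;
  IntegerVector bt_gamma(m);
  long acc_theta = 0, acc_a = 0, n_theta = 0, n_a = 0;
  std::vector<long> acc_gamma(m, 0), n_gamma(m, 0);
  int batch_no = 0;

  double cur_ll = full_loglik(adj, theta, alpha);
  if (!R_finite(cur_ll)) stop("non-finite log-likelihood at initial values");

  const int total = burn_in + draws;
  int kept = 0;
  for (int it = 0; it < total; ++it) {
    const bool sampling = it >= burn_in;

    // theta
    {
      const double prop = theta + exp(ls_theta) * R::norm_rand();
      const double ll_prop = full_loglik(adj, prop, alpha);
      const double dlp = ll_prop - cur_ll -
          0.5 * tau_theta * (prop * prop - theta * theta);
      if (log(R::unif_rand()) < dlp) {
        theta = prop;
        cur_ll = ll_prop;
        ++bt_theta;
        if (sampling) ++acc_theta;
      }
      if (sampling) ++n_theta;
    }

    // gamma components: sociality shifts by delta * X[, k]
    for (int k = 0; k < m; ++k) {
      const double delta = exp(ls_gamma[k]) * R::norm_rand();
      const double prop = gamma[k] + delta;
      NumericVector alpha_prop = clone(alpha);
      for (int i = 0; i < n; ++i) alpha_prop[i] += delta * X(i, k);
      const double ll_prop = full_loglik(adj, theta, alpha_prop);
      const double dlp = ll_prop - cur_ll -
          0.5 * tau_gamma * (prop * prop - gamma[k] * gamma[k]);
      if (log(R::unif_rand()) < dlp) {
        gamma[k] = prop;
        alpha = alpha_prop;
        cur_ll = ll_prop;
        ++bt_gamma[k];
        if (sampling) ++acc_gamma[k];
      }
      if (sampling) ++n_gamma[k];
    }

    // random effects: full conditional touches only node i's dyads
    for (int i = 0; i < n; ++i) {
      const double delta = exp(ls_a) * R::norm_rand();
      const double prop_a = a[i] + delta;
      const double prop_alpha = alpha[i] + delta;
      const double ll_old = node_loglik(adj, theta, alpha, i, alpha[i]);
      const double ll_new = node_loglik(adj, theta, alpha, i, prop_alpha);
      const double dlp = ll_new - ll_old -
          0.5 * tau_a * (prop_a * prop_a - a[i] * a[i]);
      if (log(R::unif_rand()) < dlp) {
        a[i] = prop_a;
        alpha[i] = prop_alpha;
        cur_ll += ll_new - ll_old;
        ++bt_a;
        if (sampling) ++acc_a;
      }
      if (sampling) ++n_a;
    }

    // conjugate precision draws
    tau_theta = rgamma_rate(a0 + 0.5, b0 + 0.5 * theta * theta);
    double ss_g = 0.0;
    for (int k = 0; k < m; ++k) ss_g += gamma[k] * gamma[k];
    tau_gamma = rgamma_rate(a0 + 0.5 * m, b0 + 0.5 * ss_g);
    double ss_a = 0.0;
    for (int i = 0; i < n; ++i) ss_a += a[i] * a[i];
    tau_a = rgamma_rate(a0 + 0.5 * n, b0 + 0.5 * ss_a);

    // burn-in-only scale adaptation toward 0.44 acceptance
    if (adapt && !sampling && ((it + 1) % batch == 0)) {
      ++batch_no;
      const double step = std::min(0.25, 2.0 / sqrt((double)batch_no));
      ls_theta += step * ((double)bt_theta / batch - 0.44);
      for (int k = 0; k < m; ++k) {
        ls_gamma[k] += step * ((double)bt_gamma[k] / batch - 0.44);
        bt_gamma[k] = 0;
      }
      ls_a += step * ((double)bt_a / (batch * (double)n) - 0.44);
      bt_theta = 0;
      bt_a = 0;
    }

    if (sampling) {
      const int d = it - burn_in;
      if ((d + 1) % thin == 0 && kept < n_keep) {
        out_theta[kept] = theta;
        for (int k = 0; k < m; ++k) out_gamma(kept, k) = gamma[k];
        for (int i = 0; i < n; ++i) out_a(kept, i) = a[i];
        out_tau_theta[kept] = tau_theta;
        out_tau_gamma[kept] = tau_gamma;
        out_tau_a[kept] = tau_a;
        ++kept;
      }
    }
  }

  NumericVector acc_rate_gamma(m);
  for (int k = 0; k < m; ++k) {
    acc_rate_gamma[k] = n_gamma[k] ? (double)acc_gamma[k] / n_gamma[k] : NA_REAL;
  }

  return List::create(
      _["theta"] = out_theta, _["gamma"] = out_gamma, _["a"] = out_a,
      _["tau_theta"] = out_tau_theta, _["tau_gamma"] = out_tau_gamma,
      _["tau_a"] = out_tau_a,
      _["accept"] = List::create(
          _["theta"] = n_theta ? (double)acc_theta / n_theta : NA_REAL,
          _["gamma"] = acc_rate_gamma,
          _["a"] = n_a ? (double)acc_a / n_a : NA_REAL),
      _["scales"] = List::create(
          _["theta"] = exp(ls_theta), _["gamma"] = exp(ls_gamma),
          _["a"] = exp(ls_a)));
}
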