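// Adaptive Metropolis-within-Gibbs sampler for the hierarchical beta
// regression with a piecewise random intercept.
//
// Blocks: each fixed effect, mu_b, each non-singleton random intercept,
// log(phi), log(sigma2_b).  Proposal scales adapt toward ~35% acceptance
// during burn-in only, so the post-burn-in chain is a valid Markov chain.
//
// Uses R's RNG (deterministic under set.seed on the R side).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double row_loglik(double logy, double log1my, double eta,
                                double phi, double lgam_phi) {
  double mu = 1.0 / (1.0 + std::exp(-eta));
  if (mu < 1e-12) mu = 1e-12;
  if (mu > 1.0 - 1e-12) mu = 1.0 - 1e-12;
  double a = mu * phi, b = (1.0 - mu) * phi;
  return (a - 1.0) * logy + (b - 1.0) * log1my -
         R::lgammafn(a) - R::lgammafn(b) + lgam_phi;
}

// [[Rcpp::export]]
List sample_chain_cpp(NumericVector y, NumericMatrix X,
                      IntegerVector participant,  // 1-based, per row
                      NumericVector singleton,    // per participant, 0/1
                      List priors, List init,
                      int n_burn, int n_iter, int adapt_interval) {
  const int n = y.size();
  const int p = X.ncol();
  const int m = singleton.size();

  const double beta_var = as<double>(priors["beta_var"]);
  const double mu_b_var = as<double>(priors["mu_b_var"]);
  const double phi_shape = as<double>(priors["phi_shape"]);
  const double phi_scale = as<double>(priors["phi_scale"]);
  const double tau_shape = as<double>(priors["tau_shape"]);
  const double tau_scale = as<double>(priors["tau_scale"]);

  NumericVector beta = clone(as<NumericVector>(init["beta"]));
  double mu_b = as<double>(init["mu_b"]);
  NumericVector b = clone(as<NumericVector>(init["b"]));
  double phi = as<double>(init["phi"]);
  double sigma2_b = as<double>(init["sigma2_b"]);
  double lphi = std::log(phi), lsig = std::log(sigma2_b);

  // Row bookkeeping.
  std::vector<double> logy(n), log1my(n);
  for (int i = 0; i < n; ++i) {
    logy[i] = std::log(y[i]);
    log1my[i] = std::log1p(-y[i]);
  }
  std::vector<std::vector<int> > rows_of(m);
  std::vector<int> single_rows;
  for (int i = 0; i < n; ++i) {
    int pi = participant[i] - 1;
    rows_of[pi].push_back(i);
    if (singleton[pi] == 1.0) single_rows.push_back(i);
  }
  std::vector<int> multi_idx;
  for (int j = 0; j < m; ++j)
    if (singleton[j] == 0.0) multi_idx.push_back(j);
  const int m_multi = (int)multi_idx.size();
  // Non-zero rows per column (dummy columns touch only a subset of rows).
  std::vector<std::vector<int> > col_rows(p);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i)
      if (X(i, k) != 0.0) col_rows[k].push_back(i);

  // Linear predictor and per-row log likelihood caches.
  std::vector<double> eta(n), rowll(n);
  double lgam_phi = R::lgammafn(phi);
  for (int i = 0; i < n; ++i) {
    int pi = participant[i] - 1;
    double e = (singleton[pi] == 1.0) ? mu_b : b[pi];
    for (int k = 0; k < p; ++k) e += X(i, k) * beta[k];
    eta[i] = e;
    rowll[i] = row_loglik(logy[i], log1my[i], e, phi, lgam_phi);
  }

  // One proposal scale per block: p betas, mu_b, m_multi intercepts,
  // lphi, lsig.
  const int n_blocks = p + 1 + m_multi + 2;
  std::vector<double> lscale(n_blocks);
  for (int k = 0; k < p + 1 + m_multi; ++k) lscale[k] = std::log(0.1);
  lscale[n_blocks - 2] = std::log(0.3);
  lscale[n_blocks - 1] = std::log(0.5);
  std::vector<int> acc_batch(n_blocks, 0), acc_keep(n_blocks, 0);
  const double target = 0.35;

  const int n_total = n_burn + n_iter;
  NumericMatrix draws(n_iter, p + 3 + m);
  NumericVector deviance(n_iter);

  std::vector<double> prop_ll; prop_ll.reserve(n);
  int batch = 0;

  for (int iter = 0; iter < n_total; ++iter) {
    const bool burnin = iter < n_burn;

    // --- fixed effects, one scalar update each ---
    for (int k = 0; k < p; ++k) {
      double s = std::exp(lscale[k]);
      double prop = beta[k] + s * R::norm_rand();
      double d = prop - beta[k];
      const std::vector<int>& rws = col_rows[k];
      double dll = 0.0;
      prop_ll.resize(rws.size());
      for (size_t r = 0; r < rws.size(); ++r) {
        int i = rws[r];
        double ll = row_loglik(logy[i], log1my[i], eta[i] + d * X(i, k),
                               phi, lgam_phi);
        prop_ll[r] = ll;
        dll += ll - rowll[i];
      }
      double dprior = -(prop * prop - beta[k] * beta[k]) / (2.0 * beta_var);
      if (std::log(R::unif_rand()) < dll + dprior) {
        beta[k] = prop;
        for (size_t r = 0; r < rws.size(); ++r) {
          int i = rws[r];
          eta[i] += d * X(i, k);
          rowll[i] = prop_ll[r];
        }
        acc_batch[k]++; if (!burnin) acc_keep[k]++;
      }
    }

    // --- mu_b (enters singleton rows and the b_i prior) ---
    {
      int kb = p;
      double s = std::exp(lscale[kb]);
      double prop = mu_b + s * R::norm_rand();
      double d = prop - mu_b;
      double dll = 0.0;
      prop_ll.resize(single_rows.size());
      for (size_t r = 0; r < single_rows.size(); ++r) {
        int i = single_rows[r];
        double ll = row_loglik(logy[i], log1my[i], eta[i] + d, phi, lgam_phi);
        prop_ll[r] = ll;
        dll += ll - rowll[i];
      }
      double dprior = -(prop * prop - mu_b * mu_b) / (2.0 * mu_b_var);
      for (int j = 0; j < m_multi; ++j) {
        double bi = b[multi_idx[j]];
        dprior += (-(bi - prop) * (bi - prop) + (bi - mu_b) * (bi - mu_b)) /
                  (2.0 * sigma2_b);
      }
      if (std::log(R::unif_rand()) < dll + dprior) {
        mu_b = prop;
        for (size_t r = 0; r < single_rows.size(); ++r) {
          int i = single_rows[r];
          eta[i] += d;
          rowll[i] = prop_ll[r];
        }
        acc_batch[kb]++; if (!burnin) acc_keep[kb]++;
      }
    }

    // --- random intercepts ---
    for (int j = 0; j < m_multi; ++j) {
      int pi = multi_idx[j];
      int kb = p + 1 + j;
      double s = std::exp(lscale[kb]);
      double prop = b[pi] + s * R::norm_rand();
      double d = prop - b[pi];
      const std::vector<int>& rws = rows_of[pi];
      double dll = 0.0;
      prop_ll.resize(rws.size());
      for (size_t r = 0; r < rws.size(); ++r) {
        int i = rws[r];
        double ll = row_loglik(logy[i], log1my[i], eta[i] + d, phi, lgam_phi);
        prop_ll[r] = ll;
        dll += ll - rowll[i];
      }
      double dprior = (-(prop - mu_b) * (prop - mu_b) +
                       (b[pi] - mu_b) * (b[pi] - mu_b)) / (2.0 * sigma2_b);
      if (std::log(R::unif_rand()) < dll + dprior) {
        b[pi] = prop;
        for (size_t r = 0; r < rws.size(); ++r) {
          int i = rws[r];
          eta[i] += d;
          rowll[i] = prop_ll[r];
        }
        acc_batch[kb]++; if (!burnin) acc_keep[kb]++;
      }
    }

    // --- log(phi) ---
    {
      int kb = p + 1 + m_multi;
      double s = std::exp(lscale[kb]);
      double prop_l = lphi + s * R::norm_rand();
      double prop_phi = std::exp(prop_l);
      double prop_lgam = R::lgammafn(prop_phi);
      double dll = 0.0;
      prop_ll.resize(n);
      for (int i = 0; i < n; ++i) {
        double ll = row_loglik(logy[i], log1my[i], eta[i], prop_phi,
                               prop_lgam);
        prop_ll[i] = ll;
        dll += ll - rowll[i];
      }
      // Gamma(shape, scale) prior on phi plus the log-transform Jacobian.
      double dprior = phi_shape * (prop_l - lphi) -
                      (prop_phi - phi) / phi_scale;
      if (std::log(R::unif_rand()) < dll + dprior) {
        lphi = prop_l; phi = prop_phi; lgam_phi = prop_lgam;
        for (int i = 0; i < n; ++i) rowll[i] = prop_ll[i];
        acc_batch[kb]++; if (!burnin) acc_keep[kb]++;
      }
    }

    // --- log(sigma2_b): gamma prior on tau = 1/sigma2_b ---
    {
      int kb = p + 1 + m_multi + 1;
      double s = std::exp(lscale[kb]);
      double prop_l = lsig + s * R::norm_rand();
      double prop_s2 = std::exp(prop_l);
      double ssq = 0.0;
      for (int j = 0; j < m_multi; ++j) {
        double d = b[multi_idx[j]] - mu_b;
        ssq += d * d;
      }
      double cur_tau = 1.0 / sigma2_b, prop_tau = 1.0 / prop_s2;
      double cur_lp = -0.5 * m_multi * lsig - 0.5 * ssq / sigma2_b +
                      tau_shape * std::log(cur_tau) - cur_tau / tau_scale;
      double prop_lp = -0.5 * m_multi * prop_l - 0.5 * ssq / prop_s2 +
                       tau_shape * std::log(prop_tau) - prop_tau / tau_scale;
      if (std::log(R::unif_rand()) < prop_lp - cur_lp) {
        lsig = prop_l; sigma2_b = prop_s2;
        acc_batch[kb]++; if (!burnin) acc_keep[kb]++;
      }
    }

    // --- adaptation (burn-in only) ---
    if (burnin && adapt_interval > 0 && (iter + 1) % adapt_interval == 0) {
      batch++;
      double step = std::min(0.25, 1.0 / std::sqrt((double)batch));
      for (int kb = 0; kb < n_blocks; ++kb) {
        double rate = (double)acc_batch[kb] / adapt_interval;
        lscale[kb] += step * (rate - target);
        acc_batch[kb] = 0;
      }
    }

    // --- store ---
    if (!burnin) {
      int it = iter - n_burn;
      for (int k = 0; k < p; ++k) draws(it, k) = beta[k];
      draws(it, p) = mu_b;
      draws(it, p + 1) = phi;
      draws(it, p + 2) = sigma2_b;
      for (int j = 0; j < m; ++j)
        draws(it, p + 3 + j) = (singleton[j] == 1.0) ? mu_b : b[j];
      double ll = 0.0;
      for (int i = 0; i < n; ++i) ll += rowll[i];
      deviance[it] = -2.0 * ll;
    }

    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc(n_blocks);
  for (int kb = 0; kb < n_blocks; ++kb)
    acc[kb] = n_iter > 0 ? (double)acc_keep[kb] / n_iter : NA_REAL;

  return List::create(
    _["draws"] = draws,
    _["deviance"] = deviance,
    _["accept"] = acc,
    _["n_multi"] = m_multi
  );
}
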