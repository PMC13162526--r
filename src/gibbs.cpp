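#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for whole-genome regression
//   y = 1*mu + Z b + e,  e ~ N(0, I sigma2e)
// with the marker-effect prior selected by `family`:
//   1 bayes_a : b_j ~ N(0, v_j), v_j ~ scaled-inv-chisq(dfb, sb)  (scaled-t)
//   2 bayes_b : spike at 0 with prob pi, slab as bayes_a
//   3 bayes_c : spike at 0 with prob pi, slab N(0, v) common v
//   4 brr     : b_j ~ N(0, v) common v ~ scaled-inv-chisq(dfb, sb)
//   5 bl      : b_j ~ N(0, tau2_j sigma2e), 1/tau2_j inverse-Gaussian,
//               lambda2 ~ Gamma(bl_shape, bl_rate)
// Residual variance: sigma2e ~ scaled-inv-chisq(df0, s0).
// Uses R's RNG throughout, so set.seed() gives bit-identical chains.

static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0 || !R_finite(x)) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double rscinvchisq(double df, double scale) {
  // scaled inverse chi-square draw: df*scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_wgr_cpp")]]
List gibbs_wgr_cpp(NumericVector y, NumericMatrix Z, int family,
                   int n_iter, int burn_in,
                   double df0, double s0, double dfb, double sb,
                   double pi_zero, double bl_shape, double bl_rate) {
  const int n = y.size();
  const int m = Z.ncol();
  if (Z.nrow() != n) stop("rows of Z must match y");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  std::vector<double> zz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* zj = &Z(0, j);
    for (int i = 0; i < n; ++i) s += zj[i] * zj[i];
    zz[j] = s;
  }

  std::vector<double> b(m, 0.0);
  std::vector<double> v(m, sb);       // per-marker variances (bayes_a/b)
  std::vector<int> delta(m, 1);       // inclusion indicators (bayes_b/c)
  std::vector<double> tau2(m, 1.0);   // BL latent scales
  double v_common = sb;               // brr / bayes_c slab variance
  double lambda2 = (bl_rate > 0.0) ? bl_shape / bl_rate : 1.0;
  double mu = mean(y);
  double sigma2e = 0.0;
  for (int i = 0; i < n; ++i) sigma2e += (y[i] - mu) * (y[i] - mu);
  sigma2e = std::max(sigma2e / std::max(n - 1, 1) / 2.0, 1e-8);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int n_keep = n_iter - burn_in;
  std::vector<double> b_sum(m, 0.0), g_sum(n, 0.0), g_sumsq(n, 0.0);
  std::vector<double> incl_sum(m, 0.0);
  NumericVector se_chain(n_keep), h2_chain(n_keep);
  double mu_sum = 0.0, varg_sum = 0.0;

  for (int it = 0; it < n_iter; ++it) {
    // --- marker effects, fixed input order ---
    for (int j = 0; j < m; ++j) {
      if (zz[j] <= 0.0) { b[j] = 0.0; continue; }
      const double* zj = &Z(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += zj[i] * e[i];
      rhs += zz[j] * b[j];
      double b_old = b[j], b_new = 0.0;

      if (family == 1 || family == 4) {           // gaussian slab, always in
        double vj = (family == 1) ? v[j] : v_common;
        double C = zz[j] + sigma2e / vj;
        b_new = rhs / C + norm_rand() * std::sqrt(sigma2e / C);
      } else if (family == 2 || family == 3) {    // spike-and-slab
        double vj = (family == 2) ? v[j] : v_common;
        double den = sigma2e + zz[j] * vj;
        double logBF = 0.5 * (std::log(sigma2e / den) +
                              rhs * rhs * vj / (sigma2e * den));
        double p1 = (1.0 - pi_zero) /
          ((1.0 - pi_zero) + pi_zero * std::exp(-logBF));
        if (unif_rand() < p1) {
          delta[j] = 1;
          double C = zz[j] + sigma2e / vj;
          b_new = rhs / C + norm_rand() * std::sqrt(sigma2e / C);
        } else {
          delta[j] = 0;
          b_new = 0.0;
        }
      } else {                                     // bayesian lasso
        double C = zz[j] + 1.0 / tau2[j];
        b_new = rhs / C + norm_rand() * std::sqrt(sigma2e / C);
      }
      if (b_new != b_old) {
        double dlt = b_new - b_old;
        for (int i = 0; i < n; ++i) e[i] -= zj[i] * dlt;
        b[j] = b_new;
      }
    }

    // --- prior-variance updates ---
    if (family == 1) {
      for (int j = 0; j < m; ++j)
        v[j] = rscinvchisq(dfb + 1.0, (dfb * sb + b[j] * b[j]) / (dfb + 1.0));
    } else if (family == 2) {
      for (int j = 0; j < m; ++j) {
        if (delta[j] == 1)
          v[j] = rscinvchisq(dfb + 1.0, (dfb * sb + b[j] * b[j]) / (dfb + 1.0));
        else
          v[j] = rscinvchisq(dfb, sb);             // refresh from the prior
      }
    } else if (family == 3 || family == 4) {
      double ssb = 0.0; int m_in = 0;
      for (int j = 0; j < m; ++j) {
        if (family == 4 || delta[j] == 1) { ssb += b[j] * b[j]; ++m_in; }
      }
      v_common = rscinvchisq(dfb + m_in, (dfb * sb + ssb) / (dfb + m_in));
    } else {
      double sum_tau2 = 0.0;
      for (int j = 0; j < m; ++j) {
        double b2 = std::max(b[j] * b[j], 1e-12);
        double inv_tau2 = rinvgauss(std::sqrt(lambda2 * sigma2e / b2), lambda2);
        tau2[j] = 1.0 / std::max(inv_tau2, 1e-12);
        sum_tau2 += tau2[j];
      }
      lambda2 = R::rgamma(bl_shape + m, 1.0 / (bl_rate + sum_tau2 / 2.0));
    }

    // --- grand mean ---
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + norm_rand() * std::sqrt(sigma2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // --- residual variance ---
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = (sse + df0 * s0) / R::rchisq((double)n + df0);
    if (!R_finite(sigma2e) || sigma2e <= 0.0)
      stop("non-finite residual variance at iteration %d", it + 1);

    // --- genetic values and h2 for this iteration ---
    double gbar = 0.0;
    std::vector<double> g(n);
    for (int i = 0; i < n; ++i) { g[i] = y[i] - mu - e[i]; gbar += g[i]; }
    gbar /= n;
    double varg = 0.0;
    for (int i = 0; i < n; ++i) varg += (g[i] - gbar) * (g[i] - gbar);
    varg /= std::max(n - 1, 1);
    double h2 = varg / (varg + sigma2e);

    if (it >= burn_in) {
      int k = it - burn_in;
      for (int j = 0; j < m; ++j) b_sum[j] += b[j];
      if (family == 2 || family == 3)
        for (int j = 0; j < m; ++j) incl_sum[j] += delta[j];
      for (int i = 0; i < n; ++i) { g_sum[i] += g[i]; g_sumsq[i] += g[i] * g[i]; }
      mu_sum += mu;
      varg_sum += varg;
      se_chain[k] = sigma2e;
      h2_chain[k] = h2;
    }
  }

  NumericVector b_mean(m), g_mean(n), g_sd(n), incl(m);
  for (int j = 0; j < m; ++j) {
    b_mean[j] = b_sum[j] / n_keep;
    incl[j] = incl_sum[j] / n_keep;
  }
  for (int i = 0; i < n; ++i) {
    g_mean[i] = g_sum[i] / n_keep;
    double vsamp = g_sumsq[i] / n_keep - g_mean[i] * g_mean[i];
    g_sd[i] = std::sqrt(std::max(vsamp, 0.0));
  }
  double se_mean = mean(se_chain);
  double h2_mean = mean(h2_chain);
  return List::create(
    _["b_mean"] = b_mean, _["mu_mean"] = mu_sum / n_keep,
    _["g_mean"] = g_mean, _["g_sd"] = g_sd,
    _["sigma2e_mean"] = se_mean, _["varg_mean"] = varg_sum / n_keep,
    _["h2_mean"] = h2_mean,
    _["sigma2e_chain"] = se_chain, _["h2_chain"] = h2_chain,
    _["inclusion"] = incl);
}
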