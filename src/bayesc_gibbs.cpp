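#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the Bayes C model
//   y = X b + sum_j w_j a_j d_j + e,  d_j ~ Bern(1 - pi),
//   a_j | d_j = 1 ~ N(0, sigma2_b)  (common effect variance),
//   pi ~ Uniform(0, 1) unless fixed,
//   sigma2_b, sigma2_e ~ scaled-inverse-chi-square.
// Uses R's RNG so chains are reproducible from set.seed() on the R side.
// [[Rcpp::export]]
List bayesc_gibbs(const NumericMatrix& W, const NumericVector& y,
                  const NumericMatrix& X, int n_iter, int burn_in, int thin,
                  double nu_b, double s2_b, double nu_e, double s2_e,
                  double pi_fixed, double sigma_b0, double sigma_e0) {
  const int n = W.nrow(), m = W.ncol(), p = X.ncol();
  std::vector<double> a(m, 0.0);
  std::vector<int> delta(m, 0);
  std::vector<double> b(p, 0.0);
  std::vector<double> wtw(m), xtx(p);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* wj = &W(0, j);
    for (int i = 0; i < n; ++i) s += wj[i] * wj[i];
    wtw[j] = s;
  }
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    const double* xk = &X(0, k);
    for (int i = 0; i < n; ++i) s += xk[i] * xk[i];
    xtx[k] = s;
  }

  double pi = (pi_fixed >= 0.0) ? pi_fixed : 0.5;
  double sigma_b = sigma_b0, sigma_e = sigma_e0;

  const int n_save = (n_iter - burn_in) / thin;
  NumericVector pi_s(n_save), sb_s(n_save), se_s(n_save), h2_s(n_save);
  std::vector<double> eff_sum(m, 0.0), inc_sum(m, 0.0), b_sum(p, 0.0);
  int isave = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects (flat prior)
    for (int k = 0; k < p; ++k) {
      if (xtx[k] <= 0.0) continue;
      const double* xk = &X(0, k);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xk[i] * e[i];
      rhs += xtx[k] * b[k];
      double bn = rhs / xtx[k] + norm_rand() * std::sqrt(sigma_e / xtx[k]);
      double diff = bn - b[k];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= diff * xk[i];
      b[k] = bn;
    }

    // SNP effects with spike-and-slab indicator
    int k_in = 0;
    double pic = std::min(std::max(pi, 1e-10), 1.0 - 1e-10);
    double log_prior_ratio = std::log(1.0 - pic) - std::log(pic);
    for (int j = 0; j < m; ++j) {
      const double c = wtw[j];
      if (c <= 0.0) {  // monomorphic in this sample: always excluded
        if (a[j] != 0.0) {
          a[j] = 0.0;
        }
        delta[j] = 0;
        continue;
      }
      const double* wj = &W(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += wj[i] * e[i];
      rhs += c * a[j];
      double v1 = c * sigma_b + sigma_e;
      double logodds = 0.5 * rhs * rhs * sigma_b / (sigma_e * v1) -
                       0.5 * std::log(v1 / sigma_e) + log_prior_ratio;
      double prob;
      if (pi_fixed == 0.0) prob = 1.0;
      else if (pi_fixed == 1.0) prob = 0.0;
      else prob = 1.0 / (1.0 + std::exp(-logodds));
      double a_new;
      int d_new;
      if (unif_rand() < prob) {
        double denom = c + sigma_e / sigma_b;
        a_new = rhs / denom + norm_rand() * std::sqrt(sigma_e / denom);
        d_new = 1;
      } else {
        a_new = 0.0;
        d_new = 0;
      }
      double diff = a_new - a[j];
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= diff * wj[i];
      a[j] = a_new;
      delta[j] = d_new;
      k_in += d_new;
    }

    // exclusion proportion (Uniform(0,1) prior => Beta posterior)
    if (pi_fixed < 0.0) pi = R::rbeta((double)(m - k_in) + 1.0,
                                      (double)k_in + 1.0);

    // variances: scaled-inverse-chi-square full conditionals
    double ssa = 0.0;
    for (int j = 0; j < m; ++j) if (delta[j]) ssa += a[j] * a[j];
    sigma_b = (ssa + nu_b * s2_b) / R::rchisq(nu_b + (double)k_in);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e = (sse + nu_e * s2_e) / R::rchisq(nu_e + (double)n);
    if (!std::isfinite(sigma_b) || !std::isfinite(sigma_e) ||
        sigma_b > 1e12 || sigma_e > 1e12) {
      stop("divergent variance draw at iteration %d "
           "(sigma2_b = %g, sigma2_e = %g)", iter, sigma_b, sigma_e);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && isave < n_save) {
      pi_s[isave] = pi;
      sb_s[isave] = sigma_b;
      se_s[isave] = sigma_e;
      // genetic values g = y - Xb - e; per-draw heritability
      double gsum = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int k = 0; k < p; ++k) xb += X(i, k) * b[k];
        double g = y[i] - xb - e[i];
        gsum += g;
        gss += g * g;
      }
      double gvar = (gss - gsum * gsum / n) / (n - 1);
      h2_s[isave] = gvar / (gvar + sigma_e);
      for (int j = 0; j < m; ++j) {
        eff_sum[j] += a[j];
        inc_sum[j] += delta[j];
      }
      for (int k = 0; k < p; ++k) b_sum[k] += b[k];
      ++isave;
    }
  }

  NumericVector eff(m), inc(m), bm(p);
  for (int j = 0; j < m; ++j) {
    eff[j] = eff_sum[j] / n_save;
    inc[j] = inc_sum[j] / n_save;
  }
  for (int k = 0; k < p; ++k) bm[k] = b_sum[k] / n_save;
  return List::create(
    _["pi_samples"] = pi_s, _["sigma2_b_samples"] = sb_s,
    _["sigma2_e_samples"] = se_s, _["h2_samples"] = h2_s,
    _["effect_means"] = eff, _["inclusion_probs"] = inc,
    _["fixed_effect_means"] = bm);
}
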