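#include <Rcpp.h>
using namespace Rcpp;

// Gibbs samplers for whole-genome regression on allele dosages.
// Model codes: 1 = BRR, 2 = BayesA, 3 = BayesB, 4 = BayesC, 5 = Bayesian LASSO.
// Priors follow the standard hierarchy: beta_j | sigma2_j ~ N(0, sigma2_j)
// with sigma2_j common (BRR), per-marker scaled-inv-chisq (BayesA), a
// spike-and-slab mixture with point mass at zero (BayesB per-marker slab,
// BayesC common slab), or sigma2_eps * tau2_j with tau2_j ~ Exp(lambda2/2)
// (Bayesian LASSO, Park-Casella). Residual variance is scaled-inv-chisq in
// all models. Uses R's RNG so set.seed() controls the chain.

static double rinvchisq1(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// inverse-Gaussian sampler (Michael, Schucany & Haas)
static double rinvgauss1(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".wgr_gibbs")]]
List wgr_gibbs(NumericVector y, NumericMatrix X, int model,
               int niter, int burnin, int thin,
               double df_beta, double S_beta, double df_eps, double S_eps,
               double pi_spike, double lambda2, double lambda_shape,
               double lambda_rate, bool update_lambda,
               double fixed_s2b, double fixed_s2e, bool store_beta) {
  const int n = y.size(), p = X.ncol();
  std::vector<double> xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(p, 0.0), s2j(p), tau2(p, 1.0);
  std::vector<int> in_slab(p, 1);
  double s2b = (fixed_s2b > 0.0) ? fixed_s2b : S_beta;
  for (int j = 0; j < p; ++j) s2j[j] = s2b;
  double s2e = (fixed_s2e > 0.0) ? fixed_s2e : S_eps;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const int nsave = (niter - burnin + thin - 1) / thin;
  std::vector<double> sum_b(p, 0.0), sumsq_b(p, 0.0), sum_pip(p, 0.0);
  double sum_mu = 0.0, sumsq_mu = 0.0, sum_s2e = 0.0, sum_s2b = 0.0,
    sum_lambda2 = 0.0;
  NumericVector mu_samp(nsave), s2e_samp(nsave), s2b_samp(nsave);
  NumericMatrix beta_samp = store_beta ? NumericMatrix(nsave, p)
                                       : NumericMatrix(1, 1);
  int isave = 0;

  for (int it = 0; it < niter; ++it) {
    // intercept (flat prior)
    {
      double em = 0.0;
      for (int i = 0; i < n; ++i) em += e[i];
      em /= n;
      double mu_new = mu + em + norm_rand() * std::sqrt(s2e / n);
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= d;
      mu = mu_new;
    }

    // marker effects
    int nslab = 0;
    double ssb_slab = 0.0;
    for (int j = 0; j < p; ++j) {
      const double c = xtx[j];
      double r = c * beta[j];
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      double vj;                       // prior variance of beta_j
      switch (model) {
        case 1: vj = s2b; break;       // BRR common
        case 2: vj = s2j[j]; break;    // BayesA per marker
        case 3: vj = s2j[j]; break;    // BayesB slab per marker
        case 4: vj = s2b; break;       // BayesC common slab
        default: vj = s2e * tau2[j];   // BL
      }
      if (fixed_s2b > 0.0) vj = fixed_s2b;
      bool slab = true;
      if (model == 3 || model == 4) {
        if (pi_spike >= 1.0) {
          slab = false;
        } else if (pi_spike > 0.0) {
          double v0 = c * s2e;
          double v1 = c * c * vj + c * s2e;
          double lo = std::log(1.0 - pi_spike) - std::log(pi_spike);
          if (c > 0.0)
            lo += 0.5 * (std::log(v0) - std::log(v1)) +
              0.5 * r * r * (1.0 / v0 - 1.0 / v1);
          slab = (unif_rand() < 1.0 / (1.0 + std::exp(-lo)));
        }
      }
      double bnew = 0.0;
      if (slab) {
        double prec = c + s2e / vj;
        bnew = r / prec + norm_rand() * std::sqrt(s2e / prec);
        ++nslab;
        ssb_slab += bnew * bnew;
      }
      if (bnew != beta[j]) {
        double d = beta[j] - bnew;
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
        beta[j] = bnew;
      }
      in_slab[j] = slab ? 1 : 0;
    }

    // marker-variance hyperparameters
    if (fixed_s2b <= 0.0) {
      if (model == 1) {
        double ssb = 0.0;
        for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j];
        s2b = rinvchisq1(df_beta + p, (df_beta * S_beta + ssb) / (df_beta + p));
      } else if (model == 2) {
        for (int j = 0; j < p; ++j)
          s2j[j] = rinvchisq1(df_beta + 1.0,
                              (df_beta * S_beta + beta[j] * beta[j]) /
                                (df_beta + 1.0));
      } else if (model == 3) {
        for (int j = 0; j < p; ++j) {
          if (in_slab[j])
            s2j[j] = rinvchisq1(df_beta + 1.0,
                                (df_beta * S_beta + beta[j] * beta[j]) /
                                  (df_beta + 1.0));
          else
            s2j[j] = rinvchisq1(df_beta, S_beta);
        }
      } else if (model == 4) {
        s2b = rinvchisq1(df_beta + nslab,
                         (df_beta * S_beta + ssb_slab) / (df_beta + nslab));
      } else {  // BL: tau2_j, then lambda2
        double sum_tau2 = 0.0;
        for (int j = 0; j < p; ++j) {
          double b2 = beta[j] * beta[j];
          if (b2 < 1e-12) {
            tau2[j] = R::rexp(2.0 / lambda2);
          } else {
            double invtau = rinvgauss1(std::sqrt(lambda2 * s2e / b2), lambda2);
            tau2[j] = 1.0 / invtau;
          }
          sum_tau2 += tau2[j];
        }
        if (update_lambda)
          lambda2 = R::rgamma(lambda_shape + p,
                              1.0 / (lambda_rate + 0.5 * sum_tau2));
      }
    }

    // residual variance
    if (fixed_s2e <= 0.0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (model == 5) {
        double q = 0.0;
        for (int j = 0; j < p; ++j) q += beta[j] * beta[j] / tau2[j];
        s2e = rinvchisq1(df_eps + n + p,
                         (df_eps * S_eps + sse + q) / (df_eps + n + p));
      } else {
        s2e = rinvchisq1(df_eps + n, (df_eps * S_eps + sse) / (df_eps + n));
      }
    }

    // accumulate
    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        sum_b[j] += beta[j];
        sumsq_b[j] += beta[j] * beta[j];
        sum_pip[j] += in_slab[j];
      }
      sum_mu += mu; sumsq_mu += mu * mu;
      sum_s2e += s2e;
      double s2b_now = s2b;
      if (model == 2 || model == 3) {
        s2b_now = 0.0;
        for (int j = 0; j < p; ++j) s2b_now += s2j[j];
        s2b_now /= p;
      } else if (model == 5) {
        s2b_now = 0.0;
        for (int j = 0; j < p; ++j) s2b_now += s2e * tau2[j];
        s2b_now /= p;
      }
      mu_samp[isave] = mu; s2e_samp[isave] = s2e; s2b_samp[isave] = s2b_now;
      if (store_beta)
        for (int j = 0; j < p; ++j) beta_samp(isave, j) = beta[j];
      sum_s2b += s2b_now;
      sum_lambda2 += lambda2;
      ++isave;
    }
  }

  NumericVector bmean(p), bsd(p), pip(p);
  for (int j = 0; j < p; ++j) {
    bmean[j] = sum_b[j] / isave;
    double v = sumsq_b[j] / isave - bmean[j] * bmean[j];
    bsd[j] = std::sqrt(std::max(v, 0.0));
    pip[j] = sum_pip[j] / isave;
  }
  double mu_mean = sum_mu / isave;
  double mu_v = sumsq_mu / isave - mu_mean * mu_mean;

  return List::create(
    _["beta_mean"] = bmean, _["beta_sd"] = bsd, _["pip"] = pip,
    _["mu_mean"] = mu_mean,
    _["mu_sd"] = std::sqrt(std::max(mu_v, 0.0)),
    _["sigma2_eps_mean"] = sum_s2e / isave,
    _["sigma2_beta_mean"] = sum_s2b / isave,
    _["lambda2_mean"] = sum_lambda2 / isave,
    _["n_saved"] = isave,
    _["mu_samples"] = mu_samp,
    _["sigma2_eps_samples"] = s2e_samp,
    _["sigma2_beta_samples"] = s2b_samp,
    _["beta_samples"] = beta_samp);
}
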