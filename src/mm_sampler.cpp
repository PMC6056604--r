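#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for a Poisson log-linear model
// with an arbitrary number of random classifications, each single- or
// multiple-membership with a sparse weight matrix:
//
//   Y_i ~ Poisson(mu_i),  log mu_i = log t_i + x_i' beta + sum_c (W_c u_c)_i
//   u_j^(c) ~ N(0, sigma2_c),  beta_p ~ N(0, Vb),  sigma2_c ~ IG(a, b)
//
// Each beta_p and each u_j is updated by random-walk Metropolis with a
// per-parameter step size adapted toward a target acceptance rate during
// burn-in and frozen afterwards; each sigma2_c has a conjugate Gibbs draw.
// Weight matrices arrive in compressed sparse column form (dgCMatrix slots),
// so updating u_j touches only the persons with nonzero weight on unit j.
// eta and exp(eta) are maintained incrementally.

// [[Rcpp::export(name = ".mm_poisson_mcmc")]]
List mm_poisson_mcmc(IntegerVector y,
                     NumericVector log_t,
                     NumericMatrix X,
                     List cls_i,          // per classification: 0-based row indices (CSC)
                     List cls_p,          // per classification: column pointers (CSC)
                     List cls_x,          // per classification: nonzero weights
                     IntegerVector cls_J, // per classification: number of units
                     double beta_prior_var,
                     double ig_shape, double ig_rate,
                     int burnin, int n_iter, int thin,
                     LogicalVector fix_u,      // per classification: hold u at init
                     LogicalVector fix_sigma2, // per classification: hold sigma2 at init
                     List u_init,
                     NumericVector sigma2_init,
                     NumericVector beta_init,
                     int adapt_batch,
                     double adapt_target) {
  const int n = y.size();
  const int P = X.ncol();
  const int C = cls_J.size();

  // unpack sparse columns once: per classification, per unit, the member rows
  std::vector< std::vector< std::vector<int> > > col_rows(C);
  std::vector< std::vector< std::vector<double> > > col_w(C);
  for (int c = 0; c < C; ++c) {
    IntegerVector ii = cls_i[c];
    IntegerVector pp = cls_p[c];
    NumericVector xx = cls_x[c];
    int J = cls_J[c];
    col_rows[c].resize(J);
    col_w[c].resize(J);
    for (int j = 0; j < J; ++j) {
      for (int k = pp[j]; k < pp[j + 1]; ++k) {
        col_rows[c][j].push_back(ii[k]);
        col_w[c][j].push_back(xx[k]);
      }
    }
  }

  // state
  NumericVector beta = clone(beta_init);
  std::vector<NumericVector> u(C);
  NumericVector sigma2(C);
  for (int c = 0; c < C; ++c) {
    u[c] = clone(as<NumericVector>(u_init[c]));
    sigma2[c] = sigma2_init[c];
  }
  std::vector<double> eta(n), expeta(n);
  for (int i = 0; i < n; ++i) {
    double e = log_t[i];
    for (int p = 0; p < P; ++p) e += X(i, p) * beta[p];
    eta[i] = e;
  }
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < cls_J[c]; ++j)
      for (size_t k = 0; k < col_rows[c][j].size(); ++k)
        eta[col_rows[c][j][k]] += col_w[c][j][k] * u[c][j];
  for (int i = 0; i < n; ++i) expeta[i] = std::exp(eta[i]);
  std::vector<double> prop_eta(n), prop_exp(n);

  // adaptive step sizes (log scale) and batch acceptance counters
  NumericVector ls_beta(P, std::log(0.1));
  std::vector<NumericVector> ls_u(C);
  for (int c = 0; c < C; ++c) ls_u[c] = NumericVector(cls_J[c], std::log(0.5));
  NumericVector acc_beta_batch(P), acc_beta_total(P);
  std::vector<NumericVector> acc_u_batch(C), acc_u_total(C);
  for (int c = 0; c < C; ++c) {
    acc_u_batch[c] = NumericVector(cls_J[c]);
    acc_u_total[c] = NumericVector(cls_J[c]);
  }

  const int n_keep = n_iter / thin;
  NumericMatrix beta_store(n_keep, P);
  NumericMatrix sigma2_store(n_keep, C);
  std::vector<NumericMatrix> u_store(C);
  for (int c = 0; c < C; ++c) u_store[c] = NumericMatrix(n_keep, cls_J[c]);
  NumericVector dev_store(n_keep);

  int kept = 0, batch_no = 0;
  const int total_iter = burnin + n_iter;
  for (int it = 0; it < total_iter; ++it) {
    const bool adapting = it < burnin;

    // fixed effects: column-wise random-walk Metropolis
    for (int p = 0; p < P; ++p) {
      double delta = R::rnorm(0.0, std::exp(ls_beta[p]));
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        double en = eta[i] + X(i, p) * delta;
        double pe = std::exp(en);
        prop_eta[i] = en;
        prop_exp[i] = pe;
        ll += y[i] * X(i, p) * delta - (pe - expeta[i]);
      }
      double bp = beta[p], bn = bp + delta;
      ll += (bp * bp - bn * bn) / (2.0 * beta_prior_var);
      if (std::log(R::unif_rand()) < ll) {
        beta[p] = bn;
        std::swap(eta, prop_eta);
        std::swap(expeta, prop_exp);
        acc_beta_batch[p] += 1.0;
        if (!adapting) acc_beta_total[p] += 1.0;
      }
    }

    // random effects per classification
    for (int c = 0; c < C; ++c) {
      if (!fix_u[c]) {
        for (int j = 0; j < cls_J[c]; ++j) {
          const std::vector<int> &rows = col_rows[c][j];
          const std::vector<double> &w = col_w[c][j];
          double delta = R::rnorm(0.0, std::exp(ls_u[c][j]));
          double ll = 0.0;
          for (size_t k = 0; k < rows.size(); ++k) {
            int i = rows[k];
            double shift = w[k] * delta;
            ll += y[i] * shift - (std::exp(eta[i] + shift) - expeta[i]);
          }
          double uj = u[c][j], un = uj + delta;
          ll += (uj * uj - un * un) / (2.0 * sigma2[c]);
          if (std::log(R::unif_rand()) < ll) {
            u[c][j] = un;
            for (size_t k = 0; k < rows.size(); ++k) {
              int i = rows[k];
              eta[i] += w[k] * delta;
              expeta[i] = std::exp(eta[i]);
            }
            acc_u_batch[c][j] += 1.0;
            if (!adapting) acc_u_total[c][j] += 1.0;
          }
        }
      }
      if (!fix_sigma2[c]) {
        double ssq = 0.0;
        for (int j = 0; j < cls_J[c]; ++j) ssq += u[c][j] * u[c][j];
        double shape = ig_shape + 0.5 * cls_J[c];
        double rate = ig_rate + 0.5 * ssq;
        sigma2[c] = rate / R::rgamma(shape, 1.0); // 1/Gamma(shape, rate)
      }
    }

    // Roberts-Rosenthal batch adaptation, burn-in only
    if (adapting && ((it + 1) % adapt_batch == 0)) {
      ++batch_no;
      double step = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
      for (int p = 0; p < P; ++p) {
        ls_beta[p] += (acc_beta_batch[p] / adapt_batch > adapt_target) ? step : -step;
        acc_beta_batch[p] = 0.0;
      }
      for (int c = 0; c < C; ++c) {
        if (fix_u[c]) continue;
        for (int j = 0; j < cls_J[c]; ++j) {
          ls_u[c][j] += (acc_u_batch[c][j] / adapt_batch > adapt_target) ? step : -step;
          acc_u_batch[c][j] = 0.0;
        }
      }
    }

    if (it >= burnin && ((it - burnin + 1) % thin == 0)) {
      for (int p = 0; p < P; ++p) beta_store(kept, p) = beta[p];
      for (int c = 0; c < C; ++c) {
        sigma2_store(kept, c) = sigma2[c];
        for (int j = 0; j < cls_J[c]; ++j) u_store[c](kept, j) = u[c][j];
      }
      double dev = 0.0;
      for (int i = 0; i < n; ++i)
        dev += y[i] * eta[i] - expeta[i] - R::lgammafn(y[i] + 1.0);
      dev_store[kept] = -2.0 * dev;
      ++kept;
    }

    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List u_out(C), acc_u_out(C);
  for (int c = 0; c < C; ++c) {
    u_out[c] = u_store[c];
    acc_u_out[c] = acc_u_total[c] / (double)n_iter;
  }
  return List::create(
      _["beta"] = beta_store,
      _["u"] = u_out,
      _["sigma2"] = sigma2_store,
      _["deviance"] = dev_store,
      _["accept_beta"] = acc_beta_total / (double)n_iter,
      _["accept_u"] = acc_u_out);
}
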