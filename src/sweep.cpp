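#include <Rcpp.h>
using namespace Rcpp;

static inline double lbin_core(double y, double n, double p) {
  return -std::lgamma(y + 1.0) - std::lgamma(n - y + 1.0)
       + y * std::log(p) + (n - y) * std::log1p(-p);
}

// Sequential Metropolis sweep over the continuous-relaxed latent true
// counts. Each latent count y_j lives in (0, n_j) and has density
//   BinomCont(y_j | n_j, pi_j)
//   x prod over survey observations o containing j: N(val_o | S_o, kappa_o^2)
//   x (admin cells) N(logv_j | log y_j + gamma_j, sigma_y^2),
// where S_o is the sum of latent counts over the cells observation o
// aggregates. The sweep is sequential because the S_o couple cells within
// an observation; running sums are updated on acceptance. Proposals are
// random walks on logit(y/n) with per-cell adaptive log step sizes; the
// log-Jacobian log y + log(n - y) is included. Uses R's RNG.
//
// obs_ptr/obs_idx: CSR map from active cell j to the survey observation
// ids touching it (0-based, obs_ptr has length m+1).
// [[Rcpp::export]]
List y_sweep_cpp(NumericVector y, NumericVector n, NumericVector pi,
                 IntegerVector obs_ptr, IntegerVector obs_idx,
                 NumericVector obs_val, NumericVector obs_kappa,
                 NumericVector S,
                 LogicalVector has_admin, NumericVector admin_logv,
                 NumericVector admin_gamma, NumericVector sigma_y,
                 NumericVector lstep) {
  int m = y.size();
  NumericVector ynew = clone(y);
  NumericVector Snew = clone(S);
  IntegerVector acc(m);

  for (int j = 0; j < m; ++j) {
    double nj = n[j];
    double pj = pi[j];
    double yc = ynew[j];
    double w = std::log(yc) - std::log(nj - yc);
    double wp = w + std::exp(lstep[j]) * norm_rand();
    double yp = nj / (1.0 + std::exp(-wp));
    if (yp <= 0.0 || yp >= nj) continue; // numeric under/overflow guard

    // binomial + jacobian terms
    double lr = lbin_core(yp, nj, pj) + std::log(yp) + std::log(nj - yp)
              - lbin_core(yc, nj, pj) - std::log(yc) - std::log(nj - yc);

    // survey aggregate terms
    for (int k = obs_ptr[j]; k < obs_ptr[j + 1]; ++k) {
      int o = obs_idx[k];
      double k2 = obs_kappa[o] * obs_kappa[o];
      double rc = obs_val[o] - Snew[o];
      double rp = rc - (yp - yc);
      lr += (rc * rc - rp * rp) / (2.0 * k2);
    }

    // admin log-scale term
    if (has_admin[j]) {
      double sy2 = sigma_y[j] * sigma_y[j];
      double rc = admin_logv[j] - std::log(yc) - admin_gamma[j];
      double rp = admin_logv[j] - std::log(yp) - admin_gamma[j];
      lr += (rc * rc - rp * rp) / (2.0 * sy2);
    }

    if (std::log(unif_rand()) < lr) {
      for (int k = obs_ptr[j]; k < obs_ptr[j + 1]; ++k) {
        Snew[obs_idx[k]] += yp - yc;
      }
      ynew[j] = yp;
      acc[j] = 1;
    }
  }
  return List::create(_["y"] = ynew, _["S"] = Snew, _["acc"] = acc);
}

// Joint sequential sweep over (theta_j, y_j): proposes a random-walk step
// in theta and shifts y by the implied change in the binomial mean,
// y' = y + n (invlogit(theta') - invlogit(theta)) — a unit-Jacobian shear
// that carries the latent count along the ridge created by large
// exposures. The separate theta and y updates handle the orthogonal
// direction; this move is what lets biased sources trade level against
// the bias parameters. Sequential because survey sums couple cells.
// [[Rcpp::export]]
List theta_y_sweep_cpp(NumericVector theta, NumericVector mu, double sigma,
                       NumericVector y, NumericVector n,
                       IntegerVector obs_ptr, IntegerVector obs_idx,
                       NumericVector obs_val, NumericVector obs_kappa,
                       NumericVector S,
                       LogicalVector has_admin, NumericVector admin_logv,
                       NumericVector admin_gamma, NumericVector sigma_y,
                       NumericVector bin_a, NumericVector bin_b,
                       NumericVector lstep) {
  int m = y.size();
  NumericVector tnew = clone(theta);
  NumericVector ynew = clone(y);
  NumericVector Snew = clone(S);
  IntegerVector acc(m);
  double s2 = 2.0 * sigma * sigma;

  for (int j = 0; j < m; ++j) {
    double nj = n[j];
    double tc = tnew[j];
    double tp = tc + std::exp(lstep[j]) * norm_rand();
    double pc = 1.0 / (1.0 + std::exp(-tc));
    double pp = 1.0 / (1.0 + std::exp(-tp));
    double yc = ynew[j];
    double yp = yc + nj * (pp - pc);
    if (yp <= 0.0 || yp >= nj || pp <= 0.0 || pp >= 1.0) continue;

    double lr = (-(tp - mu[j]) * (tp - mu[j])
                 + (tc - mu[j]) * (tc - mu[j])) / s2
              + lbin_core(yp, nj, pp) - lbin_core(yc, nj, pc);

    // direct binomial observations on this cell's prevalence
    if (bin_b[j] > 0) {
      double sp_p = tp > 30 ? tp : std::log1p(std::exp(tp));
      double sp_c = tc > 30 ? tc : std::log1p(std::exp(tc));
      lr += bin_a[j] * (tp - tc) - bin_b[j] * (sp_p - sp_c);
    }

    for (int k = obs_ptr[j]; k < obs_ptr[j + 1]; ++k) {
      int o = obs_idx[k];
      double k2 = obs_kappa[o] * obs_kappa[o];
      double rc = obs_val[o] - Snew[o];
      double rp = rc - (yp - yc);
      lr += (rc * rc - rp * rp) / (2.0 * k2);
    }

    if (has_admin[j]) {
      double sy2 = sigma_y[j] * sigma_y[j];
      double rc = admin_logv[j] - std::log(yc) - admin_gamma[j];
      double rp = admin_logv[j] - std::log(yp) - admin_gamma[j];
      lr += (rc * rc - rp * rp) / (2.0 * sy2);
    }

    if (std::log(unif_rand()) < lr) {
      for (int k = obs_ptr[j]; k < obs_ptr[j + 1]; ++k) {
        Snew[obs_idx[k]] += yp - yc;
      }
      tnew[j] = tp;
      ynew[j] = yp;
      acc[j] = 1;
    }
  }
  return List::create(_["theta"] = tnew, _["y"] = ynew, _["S"] = Snew,
                      _["acc"] = acc);
}
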