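// Gibbs sampler for the Bernoulli-logit dose-outcome models with
// spike-and-slab priors on the subgroup coefficients.
//
// Data augmentation: omega_i ~ PG(1, x_i' beta) (Polson-Scott-Windle),
// after which beta | omega, gamma is Gaussian.  Each inclusion indicator
// gamma_l is updated from its conditional with the slab integrated out
// against the PG-augmented Gaussian form, so the sampler targets the
// exact joint posterior of (beta, gamma) with a point-mass spike at 0.
//
// The models have at most 6 coefficients, and the sampler is called
// thousands of times per simulated trial study, so all linear algebra
// uses fixed-size stack arrays (Cholesky on p <= 6).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "polya_gamma.h"

namespace {

const int PMAX = 6;

// lower Cholesky of M restricted to rows/cols `act`; returns log det(L)
double chol_small(const double M[PMAX][PMAX], const double* diag_add,
                  const int* act, int m, double L[PMAX][PMAX]) {
  double logdet = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = M[act[i]][act[j]];
      if (i == j) s += diag_add[act[i]];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        L[i][i] = std::sqrt(s);
        logdet += std::log(L[i][i]);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  return logdet;
}

// forward solve L u = r
void fwd_solve(const double L[PMAX][PMAX], const double* r, int m,
               double* u) {
  for (int i = 0; i < m; ++i) {
    double s = r[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * u[k];
    u[i] = s / L[i][i];
  }
}

// backward solve L' v = u
void bwd_solve(const double L[PMAX][PMAX], const double* u, int m,
               double* v) {
  for (int i = m - 1; i >= 0; --i) {
    double s = u[i];
    for (int k = i + 1; k < m; ++k) s -= L[k][i] * v[k];
    v[i] = s / L[i][i];
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".ss_gibbs_cpp")]]
Rcpp::List ss_gibbs_cpp(Rcpp::NumericMatrix X, Rcpp::NumericVector y,
                        Rcpp::NumericVector prior_mean,
                        Rcpp::NumericVector prior_sd,
                        Rcpp::IntegerVector spike_slab,
                        Rcpp::NumericVector p_incl,
                        int n_burn, int n_keep) {
  const int n = X.nrow(), p = X.ncol();
  if (p > PMAX) Rcpp::stop("at most 6 coefficients supported");
  Rcpp::RNGScope scope;

  double prec[PMAX], b[PMAX], logprec_half[PMAX], bPb_half[PMAX];
  for (int l = 0; l < p; ++l) {
    prec[l] = 1.0 / (prior_sd[l] * prior_sd[l]);
    b[l] = prior_mean[l];
    logprec_half[l] = 0.5 * std::log(prec[l]);
    bPb_half[l] = 0.5 * b[l] * b[l] * prec[l];
  }

  // X' kappa with kappa = y - 1/2 (fixed across iterations)
  double Xtk[PMAX];
  for (int l = 0; l < p; ++l) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, l) * (y[i] - 0.5);
    Xtk[l] = s;
  }

  int gamma[PMAX];
  for (int l = 0; l < p; ++l)
    gamma[l] = spike_slab[l] ? (R::unif_rand() < p_incl[l] ? 1 : 0) : 1;
  double beta[PMAX] = {0, 0, 0, 0, 0, 0};

  // group identical design rows (at most doses x subgroups distinct
  // rows): the PG proposal setup and the X'Omega X accumulation are then
  // per unique row rather than per observation
  std::vector<int> urow_of(n);
  std::vector<std::vector<double> > urows;
  std::vector<std::vector<int> > members;
  for (int i = 0; i < n; ++i) {
    int found = -1;
    for (size_t u = 0; u < urows.size() && found < 0; ++u) {
      bool same = true;
      for (int l = 0; l < p && same; ++l)
        if (urows[u][l] != X(i, l)) same = false;
      if (same) found = (int)u;
    }
    if (found < 0) {
      std::vector<double> row(p);
      for (int l = 0; l < p; ++l) row[l] = X(i, l);
      urows.push_back(row);
      members.push_back(std::vector<int>());
      found = (int)urows.size() - 1;
    }
    urow_of[i] = found;
    members[found].push_back(i);
  }
  const int nu_rows = (int)urows.size();
  std::vector<double> omega_sum(nu_rows);

  double XtOX[PMAX][PMAX], L[PMAX][PMAX];
  int act[PMAX];

  // log of the beta-integrated conditional for the current gamma:
  //   -log|L| + 0.5 u'u + 0.5 sum(log prec) - 0.5 sum(b^2 prec)
  // over the active set, with M = X'Omega X + P, r = X'kappa + P b
  auto log_config = [&](void) {
    int m = 0;
    double r[PMAX], u[PMAX];
    for (int l = 0; l < p; ++l)
      if (gamma[l]) act[m++] = l;
    double val = 0.0;
    for (int i = 0; i < m; ++i) {
      int l = act[i];
      r[i] = Xtk[l] + prec[l] * b[l];
      val += logprec_half[l] - bPb_half[l];
    }
    val -= chol_small(XtOX, prec, act, m, L);
    fwd_solve(L, r, m, u);
    for (int i = 0; i < m; ++i) val += 0.5 * u[i] * u[i];
    return val;
  };

  Rcpp::NumericMatrix beta_out(n_keep, p), gamma_out(n_keep, p);
  const int n_iter = n_burn + n_keep;

  for (int it = 0; it < n_iter; ++it) {
    // omega | beta, grouped by unique design row
    for (int u = 0; u < nu_rows; ++u) {
      double eta = 0.0;
      for (int l = 0; l < p; ++l) eta += urows[u][l] * beta[l];
      PG1State st;
      pg1_setup(eta, st);
      double s = 0.0;
      for (size_t ii = 0; ii < members[u].size(); ++ii) s += pg1_draw(st);
      omega_sum[u] = s;
    }
    // X' Omega X from unique rows
    for (int a = 0; a < p; ++a)
      for (int c = a; c < p; ++c) {
        double s = 0.0;
        for (int u = 0; u < nu_rows; ++u)
          s += urows[u][a] * urows[u][c] * omega_sum[u];
        XtOX[a][c] = XtOX[c][a] = s;
      }

    // gamma_l | omega, gamma_-l (beta integrated out)
    for (int l = 0; l < p; ++l) {
      if (!spike_slab[l]) continue;
      gamma[l] = 1;
      double lg1 = log_config() + std::log(p_incl[l]);
      gamma[l] = 0;
      double lg0 = log_config() + std::log1p(-p_incl[l]);
      double pr1 = 1.0 / (1.0 + std::exp(lg0 - lg1));
      gamma[l] = (R::unif_rand() < pr1) ? 1 : 0;
    }

    // beta | omega, gamma (excluded coefficients pinned at exactly 0)
    int m = 0;
    double r[PMAX], u[PMAX], mean[PMAX], z[PMAX], w[PMAX];
    for (int l = 0; l < p; ++l) {
      beta[l] = 0.0;
      if (gamma[l]) act[m++] = l;
    }
    for (int i = 0; i < m; ++i) {
      int l = act[i];
      r[i] = Xtk[l] + prec[l] * b[l];
    }
    chol_small(XtOX, prec, act, m, L);
    fwd_solve(L, r, m, u);
    bwd_solve(L, u, m, mean);
    for (int i = 0; i < m; ++i) z[i] = R::norm_rand();
    bwd_solve(L, z, m, w);
    for (int i = 0; i < m; ++i) beta[act[i]] = mean[i] + w[i];

    if (it >= n_burn) {
      int row = it - n_burn;
      for (int l = 0; l < p; ++l) {
        beta_out(row, l) = beta[l];
        gamma_out(row, l) = gamma[l];
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("beta") = beta_out,
                            Rcpp::Named("gamma") = gamma_out);
}
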