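// Polya-Gamma PG(1, z) sampling via the alternating-series rejection
// sampler of Devroye (exact; no truncation error).  Uses R's RNG so that
// set.seed() on the R side makes draws reproducible.
//
// The per-z setup (mixture weights of the proposal) is factored out so
// callers drawing many variates at the same tilting z — the Gibbs
// sampler sees at most (doses x subgroups) distinct linear predictors
// per sweep — pay it once.

#include <Rcpp.h>
#include <cmath>
#include "polya_gamma.h"

namespace {

const double TRUNC = 0.64;            // 2/pi, series crossover point
const double HALFPISQ = M_PI * M_PI / 8.0;

// piecewise coefficients a_n(x) of the J*(1, z) density series
inline double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x <= TRUNC) {
    double u = 2.0 / (M_PI * x);
    return M_PI * np5 * u * std::sqrt(u) * std::exp(-2.0 * np5 * np5 / x);
  }
  return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
}

inline double phi(double q) {  // standard normal CDF
  return 0.5 * std::erfc(-q * M_SQRT1_2);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) CDF at x, stated in terms of z
// so the z -> 0 limit is handled without forming mu = Inf
inline double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double p = phi(rx * (x * z - 1.0));
  double q = phi(-rx * (x * z + 1.0));
  if (q > 0.0) p += std::exp(2.0 * z + std::log(q));
  return p;
}

// draw from inverse-Gaussian(1/z, 1) truncated to (0, TRUNC)
double rtigauss(double z) {
  double x;
  if (z < 1.0 / TRUNC) {
    // large-mean regime: proposal is the one-sided stable-like kernel
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) break;
    }
  } else {
    double mu = 1.0 / z;
    do {
      double y = R::norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    } while (x >= TRUNC);
  }
  return x;
}

}  // namespace

void pg1_setup(double z, PG1State& st) {
  st.z = std::fabs(z) * 0.5;  // PG(1,z) = J*(1, z/2) / 4
  st.K = HALFPISQ + 0.5 * st.z * st.z;
  double logp = std::log(M_PI) - std::log(2.0 * st.K) - st.K * TRUNC;
  double logq = std::log(2.0) - st.z + std::log(pigauss(TRUNC, st.z));
  st.p_over_pq = 1.0 / (1.0 + std::exp(logq - logp));
}

double pg1_draw(const PG1State& st) {
  for (;;) {
    double x;
    if (R::unif_rand() < st.p_over_pq) {
      x = TRUNC + R::exp_rand() / st.K;      // exponential tail
    } else {
      x = rtigauss(st.z);                    // truncated inverse-Gaussian body
    }
    // alternating-series accept/reject (Devroye)
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x * 0.25;
      } else {
        s += a_coef(n, x);
        if (y > s) break;                    // reject this proposal
      }
    }
  }
}

// one PG(1, z) draw
double rpg1(double z) {
  PG1State st;
  pg1_setup(z, st);
  return pg1_draw(st);
}

//' @noRd
// [[Rcpp::export(name = ".rpg_cpp")]]
Rcpp::NumericVector rpg_cpp(Rcpp::NumericVector z) {
  int n = z.size();
  Rcpp::NumericVector out(n);
  Rcpp::RNGScope scope;
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
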