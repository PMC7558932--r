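#include <Rcpp.h>
using namespace Rcpp;

// Component-wise random-walk Metropolis for the bivariate-normal correlation
// model and the univariate normal descriptive model.
//
// Parameterisation (bivariate): theta = (mu1, mu2, log sigma1, log sigma2,
// atanh rho).  Sampling in the transformed coordinates avoids boundary
// rejections; the Jacobians (sigma_j for log sigma_j, 1 - rho^2 for atanh
// rho) are folded into the log target.
//
// Priors follow the broad data-scaled family:
//   mu_j    ~ Normal(xbar_j, (100 * s_j)^2)
//   sigma_j ~ Uniform(s_j / 1000, 1000 * s_j)
//   rho     ~ Uniform(-1, 1)
//
// The likelihood depends on the data only through sufficient statistics, so
// one target evaluation is O(1) in the sample size.
//
// All randomness comes from R's RNG (RNGScope via Rcpp attributes): chains
// are reproducible by setting R's seed before each call.

struct BiStats {
  double n, sx, sy, sxx, syy, sxy;
};

struct BiPrior {
  double m1_loc, m1_scale, m2_loc, m2_scale;
  double s1_lo, s1_hi, s2_lo, s2_hi;
};

static double logpost_bi(const double th[5], const BiStats &S, const BiPrior &P) {
  const double mu1 = th[0], mu2 = th[1];
  const double s1 = std::exp(th[2]), s2 = std::exp(th[3]);
  if (s1 < P.s1_lo || s1 > P.s1_hi || s2 < P.s2_lo || s2 > P.s2_hi)
    return R_NegInf;
  const double r = std::tanh(th[4]);
  const double omr2 = 1.0 - r * r;
  const double q11 = S.sxx - 2.0 * mu1 * S.sx + S.n * mu1 * mu1;
  const double q22 = S.syy - 2.0 * mu2 * S.sy + S.n * mu2 * mu2;
  const double q12 = S.sxy - mu1 * S.sy - mu2 * S.sx + S.n * mu1 * mu2;
  const double quad = q11 / (s1 * s1) - 2.0 * r * q12 / (s1 * s2) + q22 / (s2 * s2);
  const double ll = -S.n * (std::log(s1) + std::log(s2))
                    - 0.5 * S.n * std::log(omr2) - quad / (2.0 * omr2);
  const double d1 = (mu1 - P.m1_loc) / P.m1_scale;
  const double d2 = (mu2 - P.m2_loc) / P.m2_scale;
  // log prior in transformed coordinates: normal mu terms + Jacobians
  // (uniform sigma and rho densities are constant on their supports)
  const double lp = -0.5 * d1 * d1 - 0.5 * d2 * d2 + th[2] + th[3] + std::log(omr2);
  return ll + lp;
}

// Scale adaptation: every `batch` proposals during the adapt phase the
// proposal sd of a component is nudged so the acceptance rate settles in
// the 0.2-0.5 window; scales are frozen afterwards.
static inline void adapt_scale(double &scale, int acc, int batch) {
  const double rate = static_cast<double>(acc) / batch;
  if (rate < 0.2)
    scale *= std::exp(-0.2);
  else if (rate > 0.5)
    scale *= std::exp(0.2);
}

// [[Rcpp::export]]
NumericMatrix run_chain_bicor(NumericVector suff, NumericVector prior,
                              NumericVector init, NumericVector init_scale,
                              int n_adapt, int n_burn, int thin, int n_keep) {
  BiStats S = {suff[0], suff[1], suff[2], suff[3], suff[4], suff[5]};
  BiPrior P = {prior[0], prior[1], prior[2], prior[3],
               prior[4], prior[5], prior[6], prior[7]};
  double th[5], scale[5];
  for (int j = 0; j < 5; ++j) {
    th[j] = init[j];
    scale[j] = init_scale[j];
  }
  double lp = logpost_bi(th, S, P);
  if (!R_finite(lp)) stop("initial state has zero posterior density");

  NumericMatrix out(n_keep, 5);
  const int batch = 50;
  int acc[5] = {0, 0, 0, 0, 0};
  const int n_total = n_adapt + n_burn + thin * n_keep;
  int kept = 0;

  for (int it = 0; it < n_total && kept < n_keep; ++it) {
    const bool adapting = it < n_adapt;
    for (int j = 0; j < 5; ++j) {
      const double old = th[j];
      th[j] = old + R::rnorm(0.0, scale[j]);
      const double lp_new = logpost_bi(th, S, P);
      if (lp_new >= lp || R::unif_rand() < std::exp(lp_new - lp)) {
        lp = lp_new;
        if (adapting) ++acc[j];
      } else {
        th[j] = old;
      }
    }
    if (adapting && (it + 1) % batch == 0) {
      for (int j = 0; j < 5; ++j) {
        adapt_scale(scale[j], acc[j], batch);
        acc[j] = 0;
      }
    }
    const int post = it - (n_adapt + n_burn);
    if (post >= 0 && (post + 1) % thin == 0) {
      out(kept, 0) = th[0];
      out(kept, 1) = th[1];
      out(kept, 2) = std::exp(th[2]);
      out(kept, 3) = std::exp(th[3]);
      out(kept, 4) = std::tanh(th[4]);
      ++kept;
    }
  }
  return out;
}

struct UniStats {
  double n, sx, sxx;
};

static double logpost_uni(const double th[2], const UniStats &S,
                          double m_loc, double m_scale, double s_lo, double s_hi) {
  const double mu = th[0];
  const double s = std::exp(th[1]);
  if (s < s_lo || s > s_hi) return R_NegInf;
  const double q = S.sxx - 2.0 * mu * S.sx + S.n * mu * mu;
  const double ll = -S.n * std::log(s) - q / (2.0 * s * s);
  const double d = (mu - m_loc) / m_scale;
  return ll - 0.5 * d * d + th[1];
}

// [[Rcpp::export]]
NumericMatrix run_chain_uninorm(NumericVector suff, NumericVector prior,
                                NumericVector init, NumericVector init_scale,
                                int n_adapt, int n_burn, int thin, int n_keep) {
  UniStats S = {suff[0], suff[1], suff[2]};
  double th[2], scale[2];
  for (int j = 0; j < 2; ++j) {
    th[j] = init[j];
    scale[j] = init_scale[j];
  }
  double lp = logpost_uni(th, S, prior[0], prior[1], prior[2], prior[3]);
  if (!R_finite(lp)) stop("initial state has zero posterior density");

  NumericMatrix out(n_keep, 2);
  const int batch = 50;
  int acc[2] = {0, 0};
  const int n_total = n_adapt + n_burn + thin * n_keep;
  int kept = 0;

  for (int it = 0; it < n_total && kept < n_keep; ++it) {
    const bool adapting = it < n_adapt;
    for (int j = 0; j < 2; ++j) {
      const double old = th[j];
      th[j] = old + R::rnorm(0.0, scale[j]);
      const double lp_new = logpost_uni(th, S, prior[0], prior[1], prior[2], prior[3]);
      if (lp_new >= lp || R::unif_rand() < std::exp(lp_new - lp)) {
        lp = lp_new;
        if (adapting) ++acc[j];
      } else {
        th[j] = old;
      }
    }
    if (adapting && (it + 1) % batch == 0) {
      for (int j = 0; j < 2; ++j) {
        adapt_scale(scale[j], acc[j], batch);
        acc[j] = 0;
      }
    }
    const int post = it - (n_adapt + n_burn);
    if (post >= 0 && (post + 1) % thin == 0) {
      out(kept, 0) = th[0];
      out(kept, 1) = std::exp(th[1]);
      ++kept;
    }
  }
  return out;
}
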