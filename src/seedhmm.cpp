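#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Demographic probabilities are clamped away from {0,1} inside the
// likelihood: logit-normal random effects can propose boundary values and
// log(0) would poison the chain.
static const double P_EPS = 1e-12;

static inline double clamp01(double p) {
  if (p < P_EPS) return P_EPS;
  if (p > 1.0 - P_EPS) return 1.0 - P_EPS;
  return p;
}

static inline double invlogit(double x) {
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Forward pass over one presence/absence series (0/1, -1 = unsurveyed year).
// States: 1 = (no seeds, absent), 2 = (seeds, absent), 3 = (seeds, present).
// The initial vector (1-p0, p0(1-g), p0 g) already encodes the first
// observation through Z1 = (S0, X1); the deterministic emission is applied
// as a consistency filter at every step, a missing year sums over both
// outcomes (filter skipped).  Per-step normalization, log accumulated.
static double forward_ll(const int* y, int T, double p0, double g, double s,
                         double c) {
  p0 = clamp01(p0); g = clamp01(g); s = clamp01(s); c = clamp01(c);
  double a1 = 1.0 - p0, a2 = p0 * (1.0 - g), a3 = p0 * g;
  if (y[0] == 0) a3 = 0.0;
  else if (y[0] == 1) { a1 = 0.0; a2 = 0.0; }
  double norm = a1 + a2 + a3;
  if (norm <= 0.0) return R_NegInf;
  double ll = std::log(norm);
  a1 /= norm; a2 /= norm; a3 /= norm;

  const double q = 1.0 - (1.0 - c) * (1.0 - s);  // seeds persist or arrive
  const double r11 = 1.0 - c,               r12 = c * (1.0 - g), r13 = c * g;
  const double r21 = (1.0 - c) * (1.0 - s), r22 = q * (1.0 - g), r23 = q * g;
  const double r32 = 1.0 - g,               r33 = g;             // r31 = 0

  for (int t = 1; t < T; ++t) {
    double b1 = a1 * r11 + a2 * r21;
    double b2 = a1 * r12 + a2 * r22 + a3 * r32;
    double b3 = a1 * r13 + a2 * r23 + a3 * r33;
    if (y[t] == 0) b3 = 0.0;
    else if (y[t] == 1) { b1 = 0.0; b2 = 0.0; }
    norm = b1 + b2 + b3;
    if (norm <= 0.0) return R_NegInf;
    ll += std::log(norm);
    a1 = b1 / norm; a2 = b2 / norm; a3 = b3 / norm;
  }
  return ll;
}

// [[Rcpp::export]]
double forward_loglik_cpp(IntegerVector y, double p0, double g, double s,
                          double c) {
  int T = y.size();
  std::vector<int> yy(T);
  for (int t = 0; t < T; ++t)
    yy[t] = (y[t] == NA_INTEGER) ? -1 : y[t];
  return forward_ll(yy.data(), T, p0, g, s, c);
}

// ---------------------------------------------------------------------------
// Adaptive Metropolis-within-Gibbs sampler for the multilevel HMM.
//
// Focal demographic parameter (g, s or c) gets the full plot-covariate
// structure: logit theta_ij = X_i' alpha_j, alpha_jk ~ N(mean_jk, sigma_k^2)
// with mean_jk = alpha_bar_k (k = 0..4) or gamma_k + beta_k * m_j (k = 5..7).
// The two non-focal parameters get species logit-normal intercepts
// eta1_j ~ N(mu1, tau1^2), eta2_j ~ N(mu2, tau2^2); p0_j ~ Uniform(0,1).
// Non-focal order is the remaining two of (g, s, c) in that order.
//
// Species-level scalars move by adaptive random-walk Metropolis (target
// acceptance 0.44, Robbins-Monro on the log proposal scale during warmup);
// hyper-means are conjugate Gibbs draws, hyper-SDs are truncated
// inverse-gamma Gibbs draws (uniform prior on the SD).
// ---------------------------------------------------------------------------

struct Model {
  const int* y;      // I x J x T, plot fastest
  int I, J, T, focal;
  const double* X;   // I x 8 column-major (intercept first)
  const double* m;   // J standardized log seed mass
};

// Sum of forward log-likelihoods over plots for one species.
static double ll_species(const Model& mod, int j, const double* lpf,
                         double eta1, double eta2, double p0) {
  const double th1 = invlogit(eta1), th2 = invlogit(eta2);
  double ll = 0.0;
  std::vector<int> yy(mod.T);
  for (int i = 0; i < mod.I; ++i) {
    double g, s, c;
    double thf = invlogit(lpf[i]);
    if (mod.focal == 0)      { g = thf; s = th1; c = th2; }
    else if (mod.focal == 1) { g = th1; s = thf; c = th2; }
    else                     { g = th1; s = th2; c = thf; }
    for (int t = 0; t < mod.T; ++t)
      yy[t] = mod.y[i + mod.I * (j + mod.J * t)];
    ll += forward_ll(yy.data(), mod.T, p0, g, s, c);
  }
  return ll;
}

static inline double dnorm_log(double x, double mean, double sd) {
  double z = (x - mean) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

// Truncated draw of a random-effect SD given sum of squares over n effects;
// uniform(0, upper) prior on the SD.
static double draw_sd(int n, double ss, double upper, double cur) {
  if (n < 2) return cur;
  double a = 0.5 * (n - 1);
  if (ss < 1e-10) ss = 1e-10;
  double scale = 2.0 / ss;  // tau = 1/sd^2 ~ Gamma(a, scale), tau > 1/upper^2
  double lo = R::pgamma(1.0 / (upper * upper), a, scale, 1, 0);
  double u = lo + R::runif(0.0, 1.0) * (1.0 - lo);
  if (u >= 1.0) u = 1.0 - 1e-12;
  double tau = R::qgamma(u, a, scale, 1, 0);
  if (!R_finite(tau) || tau <= 0.0) return cur;
  return 1.0 / std::sqrt(tau);
}

// [[Rcpp::export]]
List sampler_cpp(IntegerVector yarr, int I, int J, int T, NumericMatrix X,
                 NumericVector m, int focal, int n_iter, int n_warmup,
                 double prior_sd, double sd_upper, List init, bool adapt) {
  Model mod;
  std::vector<int> ybuf(yarr.size());
  for (int k = 0; k < yarr.size(); ++k)
    ybuf[k] = (yarr[k] == NA_INTEGER) ? -1 : yarr[k];
  mod.y = ybuf.data(); mod.I = I; mod.J = J; mod.T = T; mod.focal = focal;
  mod.X = X.begin(); mod.m = m.begin();

  // state
  std::vector<double> abar = as<std::vector<double> >(init["alpha_bar"]); // 5
  std::vector<double> gam  = as<std::vector<double> >(init["gamma"]);     // 3
  std::vector<double> bet  = as<std::vector<double> >(init["beta"]);      // 3
  std::vector<double> sig  = as<std::vector<double> >(init["sigma"]);     // 8
  double mu1 = init["mu1"], mu2 = init["mu2"];
  double tau1 = init["tau1"], tau2 = init["tau2"];
  NumericMatrix A0 = init["alpha"];            // J x 8
  std::vector<double> A(J * 8);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < 8; ++k) A[j * 8 + k] = A0(j, k);
  std::vector<double> eta1 = as<std::vector<double> >(init["eta1"]);
  std::vector<double> eta2 = as<std::vector<double> >(init["eta2"]);
  std::vector<double> p0   = as<std::vector<double> >(init["p0"]);

  // focal linear predictor per (species, plot), species-major
  std::vector<double> lpf(J * I);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) {
      double v = 0.0;
      for (int k = 0; k < 8; ++k) v += X(i, k) * A[j * 8 + k];
      lpf[j * I + i] = v;
    }
  std::vector<double> ll(J);
  for (int j = 0; j < J; ++j)
    ll[j] = ll_species(mod, j, &lpf[j * I], eta1[j], eta2[j], p0[j]);

  // adaptive log proposal scales
  std::vector<double> lsA(J * 8, std::log(0.5));
  std::vector<double> lsE1(J, std::log(0.5)), lsE2(J, std::log(0.5));
  std::vector<double> lsP0(J, std::log(0.2));

  const int n_par = 24 + 11 * J;  // + lp
  NumericMatrix draws(n_iter, n_par);
  std::vector<double> cand(I);
  double n_prop = 0.0, n_acc = 0.0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    const double rate = adapt && it < n_warmup
      ? std::pow((double)(it + 1), -0.6) : 0.0;

    for (int j = 0; j < J; ++j) {
      // focal coefficients, component-wise
      for (int k = 0; k < 8; ++k) {
        double mean_jk = (k <= 4) ? abar[k] : gam[k - 5] + bet[k - 5] * m[j];
        double cur = A[j * 8 + k];
        double step = R::rnorm(0.0, std::exp(lsA[j * 8 + k]));
        double prop = cur + step;
        for (int i = 0; i < I; ++i) cand[i] = lpf[j * I + i] + X(i, k) * step;
        double llp = ll_species(mod, j, cand.data(), eta1[j], eta2[j], p0[j]);
        double lr = llp - ll[j]
          + dnorm_log(prop, mean_jk, sig[k]) - dnorm_log(cur, mean_jk, sig[k]);
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        n_prop += 1.0;
        if (R::runif(0.0, 1.0) < alpha) {
          A[j * 8 + k] = prop;
          std::copy(cand.begin(), cand.end(), lpf.begin() + j * I);
          ll[j] = llp;
          n_acc += 1.0;
        }
        if (rate > 0) lsA[j * 8 + k] += rate * (alpha - 0.44);
      }
      // non-focal species intercepts
      for (int which = 0; which < 2; ++which) {
        double cur = which == 0 ? eta1[j] : eta2[j];
        double mu = which == 0 ? mu1 : mu2;
        double tau = which == 0 ? tau1 : tau2;
        double* lsv = which == 0 ? &lsE1[j] : &lsE2[j];
        double prop = cur + R::rnorm(0.0, std::exp(*lsv));
        double llp = which == 0
          ? ll_species(mod, j, &lpf[j * I], prop, eta2[j], p0[j])
          : ll_species(mod, j, &lpf[j * I], eta1[j], prop, p0[j]);
        double lr = llp - ll[j] + dnorm_log(prop, mu, tau)
          - dnorm_log(cur, mu, tau);
        double alpha = lr >= 0 ? 1.0 : std::exp(lr);
        n_prop += 1.0;
        if (R::runif(0.0, 1.0) < alpha) {
          if (which == 0) eta1[j] = prop; else eta2[j] = prop;
          ll[j] = llp;
          n_acc += 1.0;
        }
        if (rate > 0) *lsv += rate * (alpha - 0.44);
      }
      // p0, flat prior on (0,1)
      {
        double cur = p0[j];
        double prop = cur + R::rnorm(0.0, std::exp(lsP0[j]));
        double alpha = 0.0;
        n_prop += 1.0;
        if (prop > 0.0 && prop < 1.0) {
          double llp = ll_species(mod, j, &lpf[j * I], eta1[j], eta2[j], prop);
          double lr = llp - ll[j];
          alpha = lr >= 0 ? 1.0 : std::exp(lr);
          if (R::runif(0.0, 1.0) < alpha) {
            p0[j] = prop; ll[j] = llp; n_acc += 1.0;
          }
        }
        if (rate > 0) lsP0[j] += rate * (alpha - 0.44);
      }
    }

    // conjugate Gibbs: hyper-means
    const double pr = 1.0 / (prior_sd * prior_sd);
    for (int k = 0; k < 5; ++k) {
      double s2 = sig[k] * sig[k], sum = 0.0;
      for (int j = 0; j < J; ++j) sum += A[j * 8 + k];
      double prec = J / s2 + pr;
      abar[k] = R::rnorm((sum / s2) / prec, 1.0 / std::sqrt(prec));
    }
    for (int k = 5; k < 8; ++k) {
      int kk = k - 5;
      double s2 = sig[k] * sig[k];
      double sum = 0.0;
      for (int j = 0; j < J; ++j) sum += A[j * 8 + k] - bet[kk] * m[j];
      double prec = J / s2 + pr;
      gam[kk] = R::rnorm((sum / s2) / prec, 1.0 / std::sqrt(prec));
      double sxx = 0.0, sxy = 0.0;
      for (int j = 0; j < J; ++j) {
        sxx += m[j] * m[j];
        sxy += m[j] * (A[j * 8 + k] - gam[kk]);
      }
      prec = sxx / s2 + pr;
      bet[kk] = R::rnorm((sxy / s2) / prec, 1.0 / std::sqrt(prec));
    }
    // hyper-SDs (uniform prior on SD -> truncated inverse-gamma on variance)
    for (int k = 0; k < 8; ++k) {
      double ss = 0.0;
      for (int j = 0; j < J; ++j) {
        double mean_jk = (k <= 4) ? abar[k] : gam[k - 5] + bet[k - 5] * m[j];
        double d = A[j * 8 + k] - mean_jk;
        ss += d * d;
      }
      sig[k] = draw_sd(J, ss, sd_upper, sig[k]);
    }
    for (int which = 0; which < 2; ++which) {
      std::vector<double>& e = which == 0 ? eta1 : eta2;
      double& mu = which == 0 ? mu1 : mu2;
      double& tau = which == 0 ? tau1 : tau2;
      double t2 = tau * tau, sum = 0.0;
      for (int j = 0; j < J; ++j) sum += e[j];
      double prec = J / t2 + pr;
      mu = R::rnorm((sum / t2) / prec, 1.0 / std::sqrt(prec));
      double ss = 0.0;
      for (int j = 0; j < J; ++j) { double d = e[j] - mu; ss += d * d; }
      tau = draw_sd(J, ss, sd_upper, tau);
    }

    // joint log-density for monitoring
    double lp = 0.0;
    for (int j = 0; j < J; ++j) lp += ll[j];
    for (int k = 0; k < 5; ++k) lp += dnorm_log(abar[k], 0.0, prior_sd);
    for (int k = 0; k < 3; ++k) lp += dnorm_log(gam[k], 0.0, prior_sd)
      + dnorm_log(bet[k], 0.0, prior_sd);
    lp += dnorm_log(mu1, 0.0, prior_sd) + dnorm_log(mu2, 0.0, prior_sd);
    lp -= 10.0 * std::log(sd_upper);  // 8 sigmas + 2 taus, uniform
    for (int j = 0; j < J; ++j) {
      for (int k = 0; k < 8; ++k) {
        double mean_jk = (k <= 4) ? abar[k] : gam[k - 5] + bet[k - 5] * m[j];
        lp += dnorm_log(A[j * 8 + k], mean_jk, sig[k]);
      }
      lp += dnorm_log(eta1[j], mu1, tau1) + dnorm_log(eta2[j], mu2, tau2);
    }

    // store
    int c0 = 0;
    for (int k = 0; k < 5; ++k) draws(it, c0++) = abar[k];
    for (int k = 0; k < 3; ++k) draws(it, c0++) = gam[k];
    for (int k = 0; k < 3; ++k) draws(it, c0++) = bet[k];
    for (int k = 0; k < 8; ++k) draws(it, c0++) = sig[k];
    draws(it, c0++) = mu1; draws(it, c0++) = tau1;
    draws(it, c0++) = mu2; draws(it, c0++) = tau2;
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < 8; ++k) draws(it, c0++) = A[j * 8 + k];
    for (int j = 0; j < J; ++j) draws(it, c0++) = eta1[j];
    for (int j = 0; j < J; ++j) draws(it, c0++) = eta2[j];
    for (int j = 0; j < J; ++j) draws(it, c0++) = p0[j];
    draws(it, c0++) = lp;
  }

  return List::create(_["draws"] = draws,
                      _["accept_rate"] = n_acc / n_prop);
}
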