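// Wiener first-passage-time density, diffusion simulation, and the
// RL-DDM trial-sequence likelihood.
//
// Conventions (documented in ?wiener_logpdf and the methods vignette):
//   * diffusion coefficient fixed to 1 (Stan-style scale convention);
//   * boundaries at 0 (lower) and alpha (upper), start point z = beta*alpha;
//   * upper boundary == choice of the high-contingency option.
//
// The density uses the dual small-time / large-time infinite-series
// representations with adaptive truncation to absolute tolerance 1e-7
// and the analytic term-count switch rule.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double WIENER_EPS = 1e-7;

// Log of the standardized first-passage density f(tt; w) for a zero-drift
// unit-diffusion process on (0, 1) started at w, evaluated at scaled time
// tt = t / alpha^2, for absorption at the LOWER boundary. Computed fully in
// log space so extreme parameter regions (tiny tt, huge tt) stay finite and
// correctly ordered instead of saturating at a floor.
// force_method: 0 = analytic switch, 1 = small-time, 2 = large-time.
static double fpt_std_log(double tt, double w, int force_method) {
  if (tt <= 0.0) return R_NegInf;

  // required series lengths (adaptive truncation at WIENER_EPS)
  double ks = 2.0, kl = 1.0;
  double arg_s = 2.0 * WIENER_EPS * std::sqrt(2.0 * M_PI * tt);
  if (arg_s < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(arg_s));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  }
  double arg_l = M_PI * tt * WIENER_EPS;
  if (arg_l < 1.0) {
    kl = std::sqrt(-2.0 * std::log(arg_l) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  }

  bool small_time = (force_method == 1) || (force_method == 0 && ks < kl);
  if (small_time) {
    // factor out the dominant k = 0 exponent: exp(-w^2 / (2 tt))
    int K = (int)std::ceil(ks);
    double s = 0.0;
    for (int k = -K; k <= K; ++k) {
      double a = w + 2.0 * k;
      s += a * std::exp((w * w - a * a) / (2.0 * tt));
    }
    if (s <= 0.0) s = w;  // round-off guard: keep the leading term
    return -w * w / (2.0 * tt) + std::log(s) -
           0.5 * std::log(2.0 * M_PI * tt * tt * tt);
  } else {
    // factor out the dominant k = 1 exponent: exp(-pi^2 tt / 2)
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-(double)(k * k - 1) * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    if (s <= 0.0) s = std::sin(M_PI * w) * 1e-12;  // round-off guard
    return -M_PI * M_PI * tt / 2.0 + std::log(M_PI * s);
  }
}

static double wiener_lpdf_one(double rt, int upper, double alpha, double tau,
                              double beta, double nu, int force_method) {
  double t = rt - tau;
  if (t <= 0.0) return R_NegInf;
  double w = beta, v = nu;
  if (upper) {  // reflect: upper density with (nu, beta) == lower with (-nu, 1-beta)
    w = 1.0 - beta;
    v = -nu;
  }
  double tt = t / (alpha * alpha);
  double lf = fpt_std_log(tt, w, force_method);
  return lf - 2.0 * std::log(alpha) - v * alpha * w - v * v * t / 2.0;
}

// [[Rcpp::export(name = ".wiener_lpdf_cpp")]]
NumericVector wiener_lpdf_cpp(NumericVector rt, IntegerVector upper,
                              double alpha, double tau, double beta, double nu,
                              int force_method = 0) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int up = upper.size() == 1 ? upper[0] : upper[i];
    out[i] = wiener_lpdf_one(rt[i], up, alpha, tau, beta, nu, force_method);
  }
  return out;
}

// Closed-form probability of absorption at the upper boundary.
static double p_upper_one(double alpha, double beta, double nu) {
  if (std::fabs(nu) < 1e-12) return beta;
  if (nu < 0.0) {
    // reflect to keep expm1 arguments negative
    double p_low_reflect;
    {
      double a = -2.0 * (-nu) * (1.0 - beta) * alpha;
      double b = -2.0 * (-nu) * alpha;
      p_low_reflect = std::expm1(a) / std::expm1(b);
    }
    return 1.0 - p_low_reflect;
  }
  double a = -2.0 * nu * beta * alpha;
  double b = -2.0 * nu * alpha;
  return std::expm1(a) / std::expm1(b);
}

// [[Rcpp::export(name = ".wiener_p_upper_cpp")]]
double wiener_p_upper_cpp(double alpha, double beta, double nu) {
  return p_upper_one(alpha, beta, nu);
}

// ---------------------------------------------------------------------------
// Ziggurat standard-normal sampler (Marsaglia & Tsang, 128 layers) driven by
// a 32-bit Mersenne Twister; deterministic given the seed.
// ---------------------------------------------------------------------------

struct Zig {
  uint32_t kn[128];
  double wn[128], fn[128];
  Zig() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const Zig ZIG;

static inline double runif01(std::mt19937 &rng) {
  return ((double)rng() + 0.5) * (1.0 / 4294967296.0);
}

static double rnorm_fix(std::mt19937 &rng, int32_t hz, uint32_t iz) {
  const double r = 3.442619855899;
  for (;;) {
    double x = hz * ZIG.wn[iz];
    if (iz == 0) {  // tail
      double y;
      do {
        x = -std::log(runif01(rng)) / r;
        y = -std::log(runif01(rng));
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -(r + x);
    }
    if (ZIG.fn[iz] + runif01(rng) * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    hz = (int32_t)rng();
    iz = (uint32_t)hz & 127u;
    uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (az < ZIG.kn[iz]) return hz * ZIG.wn[iz];
  }
}

static inline double rnorm_zig(std::mt19937 &rng) {
  int32_t hz = (int32_t)rng();
  uint32_t iz = (uint32_t)hz & 127u;
  uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
  if (az < ZIG.kn[iz]) return hz * ZIG.wn[iz];
  return rnorm_fix(rng, hz, iz);
}

// One Euler-Maruyama path with Brownian-bridge boundary-crossing correction.
// Returns +1 (upper) or 0 (lower) in *choice and the first-passage time
// (including tau) in *rt.
static void ddm_path(double alpha, double tau, double beta, double nu,
                     double dt, std::mt19937 &rng, int *choice, double *rt) {
  double x = beta * alpha;
  double t = 0.0;
  double sq = std::sqrt(dt);
  for (;;) {
    double xn = x + nu * dt + sq * rnorm_zig(rng);
    t += dt;
    if (xn >= alpha) { *choice = 1; *rt = tau + t; return; }
    if (xn <= 0.0)   { *choice = 0; *rt = tau + t; return; }
    // bridge correction: probability the path crossed within the step
    double du = (alpha - x) * (alpha - xn);
    if (du < 10.0 * dt && runif01(rng) < std::exp(-2.0 * du / dt)) {
      *choice = 1; *rt = tau + t; return;
    }
    double dl = x * xn;
    if (dl < 10.0 * dt && runif01(rng) < std::exp(-2.0 * dl / dt)) {
      *choice = 0; *rt = tau + t; return;
    }
    x = xn;
  }
}

// [[Rcpp::export(name = ".simulate_ddm_cpp")]]
List simulate_ddm_cpp(int n, double alpha, double tau, double beta, double nu,
                      double dt, int seed) {
  std::mt19937 rng((uint32_t)seed);
  IntegerVector choice(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    int c; double t;
    ddm_path(alpha, tau, beta, nu, dt, rng, &c, &t);
    choice[i] = c;
    rt[i] = t;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

// ---------------------------------------------------------------------------
// RL-DDM composition: Q updating (dual learning rates, optional scaled
// outcome sensitivity) feeding a linear or sigmoid value-to-drift mapping.
// ---------------------------------------------------------------------------

static inline double drift_from_q(double qh, double ql, double nu,
                                  double nu_max, int sigmoid) {
  double d = (qh - ql) * nu;
  if (!sigmoid) return d;
  return 2.0 * nu_max / (1.0 + std::exp(-d)) - nu_max;
}

// pars: eta_pos, eta_neg, rho, alpha, tau, beta, nu, nu_max (native scale)
// choice: 1 = high-contingency option (upper boundary), 0 = low.
// outcome: +1 win, -1 lose.
// Returns the per-trial log density of (choice, rt).
static void rlddm_pointwise(const int *choice, const int *outcome,
                            const double *rt, int n, const double *p,
                            int scaled, int sigmoid, double *out) {
  double eta_pos = p[0], eta_neg = p[1], rho = scaled ? p[2] : 1.0;
  double alpha = p[3], tau = p[4], beta = p[5], nu = p[6], nu_max = p[7];
  double qh = 0.0, ql = 0.0;
  for (int t = 0; t < n; ++t) {
    double drift = drift_from_q(qh, ql, nu, nu_max, sigmoid);
    out[t] = wiener_lpdf_one(rt[t], choice[t], alpha, tau, beta, drift, 0);
    double qc = choice[t] ? qh : ql;
    double delta = rho * (double)outcome[t] - qc;
    double eta = delta > 0.0 ? eta_pos : eta_neg;
    qc += eta * delta;
    if (choice[t]) qh = qc; else ql = qc;
  }
}

// [[Rcpp::export(name = ".rlddm_pointwise_cpp")]]
NumericVector rlddm_pointwise_cpp(IntegerVector choice, IntegerVector outcome,
                                  NumericVector rt, NumericVector pars,
                                  int scaled, int sigmoid) {
  int n = choice.size();
  NumericVector out(n);
  rlddm_pointwise(INTEGER(choice), INTEGER(outcome), REAL(rt), n, REAL(pars),
                  scaled, sigmoid, REAL(out));
  return out;
}

// Per-session log-likelihood for many sessions in one call.
// session: 0-based session index per trial (trials grouped or not);
// parmat: n_sessions x 8 matrix of native parameters.
// [[Rcpp::export(name = ".rlddm_loglik_multi_cpp")]]
NumericVector rlddm_loglik_multi_cpp(IntegerVector choice,
                                     IntegerVector outcome, NumericVector rt,
                                     IntegerVector session,
                                     NumericMatrix parmat, int scaled,
                                     int sigmoid) {
  int ns = parmat.nrow();
  int n = choice.size();
  NumericVector out(ns);
  // state per session
  std::vector<double> qh(ns, 0.0), ql(ns, 0.0);
  for (int t = 0; t < n; ++t) {
    int s = session[t];
    double eta_pos = parmat(s, 0), eta_neg = parmat(s, 1);
    double rho = scaled ? parmat(s, 2) : 1.0;
    double alpha = parmat(s, 3), tau = parmat(s, 4), beta = parmat(s, 5);
    double nu = parmat(s, 6), nu_max = parmat(s, 7);
    double drift = drift_from_q(qh[s], ql[s], nu, nu_max, sigmoid);
    out[s] += wiener_lpdf_one(rt[t], choice[t], alpha, tau, beta, drift, 0);
    double qc = choice[t] ? qh[s] : ql[s];
    double delta = rho * (double)outcome[t] - qc;
    qc += (delta > 0.0 ? eta_pos : eta_neg) * delta;
    if (choice[t]) qh[s] = qc; else ql[s] = qc;
  }
  return out;
}

// Pointwise log densities for one session across many parameter draws.
// parmat: n_draws x 8. Returns n_draws x n_trials matrix.
// [[Rcpp::export(name = ".rlddm_pointwise_draws_cpp")]]
NumericMatrix rlddm_pointwise_draws_cpp(IntegerVector choice,
                                        IntegerVector outcome,
                                        NumericVector rt, NumericMatrix parmat,
                                        int scaled, int sigmoid) {
  int nd = parmat.nrow();
  int n = choice.size();
  NumericMatrix out(nd, n);
  std::vector<double> p(8), ll(n);
  for (int j = 0; j < nd; ++j) {
    for (int k = 0; k < 8; ++k) p[k] = parmat(j, k);
    rlddm_pointwise(INTEGER(choice), INTEGER(outcome), REAL(rt), n, p.data(),
                    scaled, sigmoid, ll.data());
    for (int t = 0; t < n; ++t) out(j, t) = ll[t];
  }
  return out;
}

// Forward simulation of an RL-DDM agent over n test trials of the
// two-option relief gamble (win probability p_win_high for the
// high-contingency option, p_win_low for the other).
// [[Rcpp::export(name = ".rlddm_sim_agent_cpp")]]
List rlddm_sim_agent_cpp(int n_trials, double p_win_high, double p_win_low,
                         NumericVector pars, int scaled, int sigmoid,
                         double dt, int seed) {
  std::mt19937 rng((uint32_t)seed);
  double eta_pos = pars[0], eta_neg = pars[1], rho = scaled ? pars[2] : 1.0;
  double alpha = pars[3], tau = pars[4], beta = pars[5];
  double nu = pars[6], nu_max = pars[7];
  IntegerVector choice(n_trials), outcome(n_trials);
  NumericVector rt(n_trials), q_high(n_trials), q_low(n_trials),
      delta_v(n_trials);
  double qh = 0.0, ql = 0.0;
  for (int t = 0; t < n_trials; ++t) {
    q_high[t] = qh;
    q_low[t] = ql;
    double drift = drift_from_q(qh, ql, nu, nu_max, sigmoid);
    int c; double rtt;
    ddm_path(alpha, tau, beta, drift, dt, rng, &c, &rtt);
    choice[t] = c;
    rt[t] = rtt;
    double p_win = c ? p_win_high : p_win_low;
    int R = (runif01(rng) < p_win) ? 1 : -1;
    outcome[t] = R;
    double qc = c ? qh : ql;
    double delta = rho * (double)R - qc;
    delta_v[t] = delta;
    qc += (delta > 0.0 ? eta_pos : eta_neg) * delta;
    if (c) qh = qc; else ql = qc;
  }
  return List::create(_["choice"] = choice, _["outcome"] = outcome,
                      _["rt"] = rt, _["q_high"] = q_high, _["q_low"] = q_low,
                      _["delta"] = delta_v);
}
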