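#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// 7-point Gauss-Legendre nodes/weights on [-1, 1], used for the uniform
// inter-trial variability integrals over starting point (sz) and
// non-decision time (st).
static const int GLN = 7;
static const double GLX[GLN] = {
  -0.9491079123427585, -0.7415311855993945, -0.4058451513773972,
   0.0,
   0.4058451513773972,  0.7415311855993945,  0.9491079123427585 };
static const double GLW[GLN] = {
   0.1294849661688697,  0.2797053914892766,  0.3818300505051189,
   0.4179591836734694,
   0.3818300505051189,  0.2797053914892766,  0.1294849661688697 };

// First-passage density at the lower boundary for unit boundary separation,
// zero drift, start z in (0,1), at normalized time u = t / a^2.
// Series representation switches between small- and large-time expansions,
// truncated so the absolute error is below `err` (Navarro & Fuss 2009 bounds).
static double wfpt_f0(double u, double z, double err)
{
  if (u <= 0.0) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * err * std::sqrt(2.0 * M_PI * u)));
    if (ks < std::sqrt(u) + 1.0) ks = std::sqrt(u) + 1.0;
  } else {
    ks = 2.0;
  }
  if (M_PI * u * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * err) / (M_PI * M_PI * u));
    double lo = 1.0 / (M_PI * std::sqrt(u));
    if (kl < lo) kl = lo;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double p = 0.0;
  if (ks < kl) {
    int K = (int) std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (int) std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double w = z + 2.0 * k;
      p += w * std::exp(-w * w / (2.0 * u));
    }
    p /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int) std::ceil(kl);
    // sin(k*pi*z) via Chebyshev-style recurrence to avoid K transcendentals
    double s1 = std::sin(M_PI * z), c1 = std::cos(M_PI * z);
    double sk = s1, sk_1 = 0.0;
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * sk;
      double sk1 = 2.0 * c1 * sk - sk_1;
      sk_1 = sk; sk = sk1;
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// Drift factor with analytic marginalization over v ~ Normal(v, sv^2)
// (lower-boundary convention).
static inline double drift_factor(double t, double a, double z, double v, double sv)
{
  if (sv > 0.0) {
    double s2t = 1.0 + sv * sv * t;
    return std::exp((a * a * z * z * sv * sv - 2.0 * a * z * v - v * v * t)
                    / (2.0 * s2t)) / std::sqrt(s2t);
  }
  return std::exp(-a * z * v - v * v * t / 2.0);
}

// Lower-boundary first-passage density at decision time t for a single
// (z, v) configuration; sv handled analytically.
static inline double dens_lower(double t, double a, double z, double v,
                                double sv, double err)
{
  if (t <= 1e-9 || z <= 0.0 || z >= 1.0) return 0.0;
  double u = t / (a * a);
  return wfpt_f0(u, z, err) / (a * a) * drift_factor(t, a, z, v, sv);
}

// Lower-boundary density at decision time tj, averaged over the sz nodes.
// The series regime and its exponential terms depend only on u = tj / a^2,
// so they are computed once and shared across starting-point nodes; the
// large-time sin(k pi z) factors use a Chebyshev recurrence per node.
static double dens_lower_sz_avg(double tj, double a, double zz, double vv,
                                double sv, double sz, double err)
{
  double u = tj / (a * a);
  int nsz = (sz > 0.0) ? GLN : 1;

  // series truncation bounds (Navarro-Fuss), independent of z
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * err * std::sqrt(2.0 * M_PI * u)));
    if (ks < std::sqrt(u) + 1.0) ks = std::sqrt(u) + 1.0;
  } else ks = 2.0;
  if (M_PI * u * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * err) / (M_PI * M_PI * u));
    double lo = 1.0 / (M_PI * std::sqrt(u));
    if (kl < lo) kl = lo;
  } else kl = 1.0 / (M_PI * std::sqrt(u));

  double out = 0.0;
  if (ks < kl) {
    // small-time expansion: terms depend on z, no sharing available
    int K = (int) std::ceil(ks);
    int klo = -((K - 1) / 2), khi = (int) std::ceil((K - 1) / 2.0);
    double norm = 1.0 / std::sqrt(2.0 * M_PI * u * u * u) / (a * a);
    for (int k = 0; k < nsz; ++k) {
      double wk = (nsz == 1) ? 1.0 : 0.5 * GLW[k];
      double zk = (nsz == 1) ? zz : zz + 0.5 * sz * GLX[k];
      if (zk <= 0.0 || zk >= 1.0) continue;
      double p = 0.0;
      for (int m = klo; m <= khi; ++m) {
        double w = zk + 2.0 * m;
        p += w * std::exp(-w * w / (2.0 * u));
      }
      if (p > 0.0)
        out += wk * p * norm * drift_factor(tj, a, zk, vv, sv);
    }
  } else {
    // large-time expansion: exponential terms shared across z nodes
    int K = (int) std::ceil(kl);
    if (K > 64) K = 64;
    double ek[64];
    for (int m = 1; m <= K; ++m)
      ek[m - 1] = m * std::exp(-m * m * M_PI * M_PI * u / 2.0);
    double norm = M_PI / (a * a);
    for (int k = 0; k < nsz; ++k) {
      double wk = (nsz == 1) ? 1.0 : 0.5 * GLW[k];
      double zk = (nsz == 1) ? zz : zz + 0.5 * sz * GLX[k];
      if (zk <= 0.0 || zk >= 1.0) continue;
      double s1 = std::sin(M_PI * zk), c1 = std::cos(M_PI * zk);
      double sk = s1, sk_1 = 0.0, p = 0.0;
      for (int m = 1; m <= K; ++m) {
        p += ek[m - 1] * sk;
        double sk1 = 2.0 * c1 * sk - sk_1;
        sk_1 = sk; sk = sk1;
      }
      if (p > 0.0)
        out += wk * p * norm * drift_factor(tj, a, zk, vv, sv);
    }
  }
  return out;
}

// Density of the decision-time component at time t (t = rt - tr), for the
// requested boundary, marginalized over sz (uniform, width sz as a fraction
// of a) and st (uniform, width st seconds) by 7-point Gauss-Legendre, and
// over sv analytically. Upper boundary handled by the reflection
// (z, v) -> (1 - z, -v).
static double dens_decision(double t, int upper, double a, double z, double v,
                            double sv, double sz, double st, double err)
{
  double zz = upper ? 1.0 - z : z;
  double vv = upper ? -v : v;

  int nst = (st > 0.0) ? GLN : 1;

  double out = 0.0;
  for (int j = 0; j < nst; ++j) {
    double wj = (nst == 1) ? 1.0 : 0.5 * GLW[j];
    double tj = (nst == 1) ? t : t - 0.5 * st * GLX[j];
    if (tj <= 1e-9) continue;
    out += wj * dens_lower_sz_avg(tj, a, zz, vv, sv, sz, err);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, int upper, double a, double z,
                               double v, double sv, double sz, double st,
                               double err)
{
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dens_decision(t[i], upper, a, z, v, sv, sz, st, err);
  return out;
}

// Summed log-likelihood of a set of trials sharing one parameter
// configuration. rt is the observed response time; tr is subtracted inside.
// Trials whose density is zero or non-finite contribute `penalty`.
// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector upper, double a,
                      double z, double v, double tr, double sv, double sz,
                      double st, double err, double penalty)
{
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = dens_decision(rt[i] - tr, upper[i], a, z, v, sv, sz, st, err);
    if (d > 0.0 && std::isfinite(d)) ll += std::log(d);
    else ll += penalty;
  }
  return ll;
}

// Per-trial log densities (same conventions as ddm_loglik_cpp).
// [[Rcpp::export]]
NumericVector ddm_logdens_cpp(NumericVector rt, IntegerVector upper, double a,
                              double z, double v, double tr, double sv,
                              double sz, double st, double err, double penalty)
{
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d = dens_decision(rt[i] - tr, upper[i], a, z, v, sv, sz, st, err);
    out[i] = (d > 0.0 && std::isfinite(d)) ? std::log(d) : penalty;
  }
  return out;
}

// Euler-Maruyama forward simulation of the diffusion process with
// inter-trial variability and deadline censoring. choice: 1 = upper (face),
// 0 = lower (house), NA = no response before the deadline.
// [[Rcpp::export]]
List simulate_ddm_cpp(int n, double a, double z, double v, double tr,
                      double sv, double sz, double st, double dt,
                      double deadline, int seed)
{
  IntegerVector choice(n);
  NumericVector rt(n);
  std::mt19937_64 rng((uint64_t) seed);
  std::normal_distribution<double> rnorm(0.0, 1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  double sqdt = std::sqrt(dt);
  // Broadie-Glasserman-Kou continuity correction for discretely monitored
  // boundary crossing: test against boundaries moved inward by
  // 0.5826 * sigma * sqrt(dt), so the discrete walk matches the continuous
  // first-passage law at the nominal boundaries.
  double cc = 0.5826 * sqdt;

  for (int i = 0; i < n; ++i) {
    double vi = (sv > 0.0) ? v + sv * rnorm(rng) : v;
    double zi = (sz > 0.0) ? z + sz * (runif(rng) - 0.5) : z;
    double ti = (st > 0.0) ? tr + st * (runif(rng) - 0.5) : tr;
    double x = a * zi;
    double tmax = deadline - ti;
    long nstep = (long) std::floor(tmax / dt);
    long step = 0;
    int hit = -1;
    while (step < nstep) {
      x += vi * dt + sqdt * rnorm(rng);
      ++step;
      if (x >= a - cc) { hit = 1; break; }
      if (x <= cc) { hit = 0; break; }
    }
    if (hit < 0) {
      choice[i] = NA_INTEGER;
      rt[i] = NA_REAL;
    } else {
      choice[i] = hit;
      rt[i] = step * dt + ti;
    }
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
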