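#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wiener first-passage-time density (Navarro & Fuss 2009 series switch).
//
// Internal convention: bounds at 0 and a, start point w*a, within-trial noise
// sigma. Drift v is accuracy-coded (positive toward the upper/correct bound).
// The density below is for absorption at the LOWER bound; the upper bound
// follows by the reflection (v, w) -> (-v, 1 - w).
// ---------------------------------------------------------------------------

static const double SQRT_2PI = 2.5066282746310002;

// standardized density f(tau; w) for unit bound separation, unit noise,
// zero drift, computed to absolute error <= err via the cheaper of the
// small-time / large-time expansions (term counts per the error bounds).
static double fpt_tau(double tau, double w, double err) {
  if (tau <= 0.0) return 0.0;

  // number of terms needed by each representation
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * err) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + (K % 2 == 0 ? 1 : 0); ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

// density of hitting the lower bound at decision time t (no non-decision time)
static double wfpt_lower(double t, double a, double v, double w,
                         double sigma, double tol) {
  if (t <= 0.0) return 0.0;
  // rescale to unit noise
  double a_ = a / sigma, v_ = v / sigma;
  double tau = t / (a_ * a_);
  double logpre = -v_ * a_ * w - v_ * v_ * t / 2.0;
  if (logpre > 700.0) logpre = 700.0;
  double pre = std::exp(logpre) / (a_ * a_);
  if (pre <= 0.0) return 0.0;
  // absolute tolerance on the returned density -> tolerance on f(tau; w)
  double err = tol / pre;
  if (err < 1e-14) err = 1e-14;
  double f = fpt_tau(tau, w, err);
  if (f < 0.0) f = 0.0; // truncated series can go epsilon-negative
  // rescaling X -> X/sigma maps to a unit-noise process on [0, a/sigma] with
  // drift v/sigma on the SAME time axis, so no extra Jacobian in t
  return pre * f;
}

// [[Rcpp::export(name = ".wfpt_pdf_cpp")]]
NumericVector wfpt_pdf_cpp(NumericVector t, double a, double v, double w,
                           double sigma, bool upper, double tol) {
  int n = t.size();
  NumericVector out(n);
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  for (int i = 0; i < n; ++i) {
    out[i] = wfpt_lower(t[i], a, vv, ww, sigma, tol);
  }
  return out;
}

// summed log-likelihood over trials with per-trial parameters; returns -Inf
// on any invalid parameter or non-positive decision time
// [[Rcpp::export(name = ".wfpt_loglik_cpp")]]
double wfpt_loglik_cpp(NumericVector rt, LogicalVector upper,
                       NumericVector a, NumericVector v, NumericVector ter,
                       double w, double sigma, double tol) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double ai = a[a.size() == 1 ? 0 : i];
    double vi = v[v.size() == 1 ? 0 : i];
    double ti = ter[ter.size() == 1 ? 0 : i];
    if (!(ai > 0.0) || !(ti >= 0.0) || !R_finite(ai) || !R_finite(vi) || !R_finite(ti))
      return R_NegInf;
    double dt = rt[i] - ti;
    if (dt <= 1e-5) return R_NegInf;
    double vv = upper[i] ? -vi : vi;
    double ww = upper[i] ? 1.0 - w : w;
    double f = wfpt_lower(dt, ai, vv, ww, sigma, tol);
    if (!(f > 0.0)) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Seeded Euler-Maruyama simulator with optional diffusion-bridge crossing
// check (removes the leading O(sqrt(dt)) boundary-miss bias).
// Own counter-free xoshiro256++ stream so that 1e6-trial oracle runs do not
// pay R RNG call overhead; seeded deterministically from a user integer.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
      x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
      s[i] = x ^ (x >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia-Tsang ziggurat for standard normals (128 layers), tables built
// once at first use
struct ZigNormal {
  uint32_t kn[128];
  double wn[128], fn[128];
  Xoshiro rng;
  explicit ZigNormal(uint64_t seed) : rng(seed) {
    const double m1 = 2147483648.0;
    const double r = 3.442619855899;
    const double vn = 9.91256303526217e-3;
    double dn = r, tn = r;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double unif() { return rng.unif(); }
  inline double norm() {
    for (;;) {
      uint64_t u64 = rng.next();
      int32_t hz = (int32_t)(uint32_t)u64;
      uint32_t iz = (uint32_t)(u64 >> 32) & 127u;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // slow path
      const double r = 3.442619855899;
      double x, y;
      if (iz == 0) { // base strip: tail
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// [[Rcpp::export(name = ".simulate_ddm_cpp")]]
List simulate_ddm_cpp(int n, NumericVector a, NumericVector v, NumericVector ter,
                      double w, double sigma, double dt, double max_time,
                      bool bridge, double seed) {
  NumericVector rt(n);
  LogicalVector up(n);
  LogicalVector censored(n);
  ZigNormal rng((uint64_t)seed);
  double sdt = sigma * std::sqrt(dt);
  double inv2 = 1.0 / (sigma * sigma * dt);
  // bridge crossing probability is < 1e-13 when both endpoints are further
  // than 4 * sigma * sqrt(dt) from the bound, so skip the exp there
  double zone = 4.0 * sdt;
  for (int i = 0; i < n; ++i) {
    double ai = a[a.size() == 1 ? 0 : i];
    double vi = v[v.size() == 1 ? 0 : i];
    double ti = ter[ter.size() == 1 ? 0 : i];
    if (!(ai > 0.0)) stop("bound separation must be positive");
    double vdt = vi * dt;
    double x = w * ai;
    double t = 0.0;
    bool done = false, hit_up = false;
    while (!done) {
      double x1 = x + vdt + sdt * rng.norm();
      if (x1 >= ai) {
        t += dt * (ai - x) / (x1 - x);
        hit_up = true; done = true;
      } else if (x1 <= 0.0) {
        t += dt * x / (x - x1);
        hit_up = false; done = true;
      } else {
        if (bridge) {
          // prob. the bridge between x and x1 crossed a bound inside the step
          if (ai - x < zone || ai - x1 < zone) {
            double pu = std::exp(-2.0 * (ai - x) * (ai - x1) * inv2);
            if (rng.unif() < pu) { t += 0.5 * dt; hit_up = true; done = true; }
          }
          if (!done && (x < zone || x1 < zone)) {
            double pl = std::exp(-2.0 * x * x1 * inv2);
            if (rng.unif() < pl) { t += 0.5 * dt; hit_up = false; done = true; }
          }
        }
        if (!done) {
          t += dt;
          x = x1;
          if (t >= max_time) {
            censored[i] = true;
            rt[i] = max_time + ti;
            up[i] = NA_LOGICAL;
            done = true;
            t = -1.0;
          }
        }
      }
    }
    if (t >= 0.0) {
      rt[i] = t + ti;
      up[i] = hit_up;
      censored[i] = false;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = up, _["censored"] = censored);
}
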