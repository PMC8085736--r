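// Wiener first-passage-time density and diffusion path simulator.
//
// Density follows the standard small-time / large-time series expansions of
// the first-passage density of a unit-variance diffusion between absorbing
// boundaries {0, a}, with the number of terms chosen per evaluation from the
// requested truncation error (accuracy-based switch between the two series).
// Upper boundary (harmful choice) densities are obtained by the reflection
// v -> -v, w -> 1 - w of the lower-boundary form.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double WIENER_EPS = 1e-10;  // series truncation error

// density of the standardized (a = 1, v = 0) first passage at the lower
// boundary, time ts = t / a^2, relative start w
static double fpt_std(double ts, double w) {
  if (ts <= 0.0) return 0.0;
  // terms needed by each series (Navarro-Fuss style bounds)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * ts) * WIENER_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * ts *
                         std::log(2.0 * WIENER_EPS * std::sqrt(2.0 * M_PI * ts)));
    ks = std::max(ks, std::sqrt(ts) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * ts * WIENER_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * ts * WIENER_EPS) / (M_PI * M_PI * ts));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(ts)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(ts));
  }

  double f = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + 1; ++k) {
      double u = w + 2.0 * k;
      f += u * std::exp(-u * u / (2.0 * ts));
    }
    f /= std::sqrt(2.0 * M_PI * ts * ts * ts);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * ts / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

// log density of (choice, rt); choice 1 = upper/harmful, 0 = lower/helpful
double dwiener_log1(double rt, int choice, double v, double a, double z,
                    double t0) {
  double t = rt - t0;
  if (t <= 0.0 || a <= 0.0 || z <= 0.0 || z >= 1.0) return R_NegInf;
  double vv = v, w = z;
  if (choice == 1) { vv = -v; w = 1.0 - z; }
  double f = fpt_std(t / (a * a), w);
  if (f <= 0.0) return R_NegInf;
  return -vv * a * w - vv * vv * t / 2.0 - 2.0 * std::log(a) + std::log(f);
}

//' @noRd
// [[Rcpp::export(name = ".dwiener_cpp")]]
NumericVector dwiener_cpp(NumericVector rt, IntegerVector choice, double v,
                          double a, double z, double t0, bool log_d) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ld = dwiener_log1(rt[i], choice[i], v, a, z, t0);
    out[i] = log_d ? ld : std::exp(ld);
  }
  return out;
}

// ---------------------------------------------------------------------------
// fast RNG for the path simulator (xoshiro256++ + Box-Muller); seeded from R
// so that results are reproducible through the usual set.seed() discipline
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t zz = x;
      zz = (zz ^ (zz >> 30)) * 0xbf58476d1ce4e5b9ULL;
      zz = (zz ^ (zz >> 27)) * 0x94d049bb133111ebULL;
      s[i] = zz ^ (zz >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Marsaglia polar method
    if (have_spare) { have_spare = false; return spare; }
    double u, w, s2;
    do {
      u = 2.0 * unif() - 1.0;
      w = 2.0 * unif() - 1.0;
      s2 = u * u + w * w;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = w * f;
    have_spare = true;
    return u * f;
  }
};

//' @noRd
// [[Rcpp::export(name = ".rwiener_cpp")]]
List rwiener_cpp(int n, double v, double a, double z, double t0, double dt,
                 double max_t, double seed) {
  NumericVector rt(n);
  IntegerVector choice(n);
  LogicalVector censored(n);
  Xoshiro rng((uint64_t)seed);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0;
    int ch = NA_INTEGER;
    bool cen = false;
    while (true) {
      double xp = x + v * dt + sdt * rng.norm();
      t += dt;
      if (xp >= a) { ch = 1; break; }
      if (xp <= 0.0) { ch = 0; break; }
      // Brownian-bridge probability of an intra-step boundary crossing;
      // without it the Euler scheme under-detects absorptions by O(sqrt(dt))
      double p_up = std::exp(-2.0 * (a - x) * (a - xp) / dt);
      if (rng.unif() < p_up) { ch = 1; break; }
      double p_lo = std::exp(-2.0 * x * xp / dt);
      if (rng.unif() < p_lo) { ch = 0; break; }
      x = xp;
      if (t >= max_t) { cen = true; ch = xp >= a / 2.0 ? 1 : 0; break; }
    }
    rt[i] = t + t0;
    choice[i] = ch;
    censored[i] = cen;
  }
  return List::create(_["rt"] = rt, _["choice"] = choice,
                      _["censored"] = censored);
}

//' @noRd
// [[Rcpp::export(name = ".wiener_p_upper_cpp")]]
double wiener_p_upper_cpp(double v, double a, double z) {
  // closed-form absorption probability at the upper boundary
  if (std::fabs(v) < 1e-12) return z;
  double num = 1.0 - std::exp(-2.0 * v * a * z);
  double den = 1.0 - std::exp(-2.0 * v * a);
  return num / den;
}
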