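// Metropolis-within-Gibbs sampler for the hierarchical stage-modulated
// multi-attribute drift-diffusion model.
//
// Participant-level parameters are treated as draws from group-level normal
// distributions (truncated where the parameter is constrained). Participant
// parameters are updated by componentwise adaptive random-walk Metropolis
// against the Wiener likelihood; group means by conjugate (truncated) normal
// draws; group standard deviations by random-walk Metropolis on the log
// scale under a half-normal prior.
//
// Parameter layout per participant (fixed order):
//   0 v0   drift intercept
//   1 wm   drift weight per unit money difference
//   2 wp   drift weight per shock difference
//   3 dwm  stage delta of wm
//   4 dwp  stage delta of wp
//   5 a    threshold separation
//   6 da   stage delta of a
//   7 z    relative starting point
//   8 dz   stage delta of z (raw scale, clamped in the likelihood)
//   9 t0   non-decision time

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

double dwiener_log1(double rt, int choice, double v, double a, double z,
                    double t0);

namespace {

struct SRng {  // splitmix64-seeded xoshiro256++, as in wiener.cpp
  uint64_t s[4];
  explicit SRng(uint64_t seed) {
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

const int NPAR = 10;
const double Z_LO = 0.01, Z_HI = 0.99, A_MIN = 0.05;

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// per-subject log-likelihood over its trials
double subj_loglik(const double* th, const NumericVector& rt,
                   const IntegerVector& choice, const NumericVector& dm,
                   const NumericVector& ds, const IntegerVector& stage,
                   const std::vector<int>& idx) {
  double ll = 0.0;
  for (size_t j = 0; j < idx.size(); ++j) {
    int i = idx[j];
    double s = (double)stage[i];
    double v = th[0] + (th[1] + th[3] * s) * dm[i] + (th[2] + th[4] * s) * ds[i];
    double a = th[5] + th[6] * s;
    double z = clampd(th[7] + th[8] * s, Z_LO, Z_HI);
    double ld = dwiener_log1(rt[i], choice[i], v, a, z, th[9]);
    if (!R_finite(ld)) return R_NegInf;
    ll += ld;
  }
  return ll;
}

bool valid_theta(const double* th) {
  if (th[5] < A_MIN || th[5] + th[6] < A_MIN) return false;
  if (th[7] <= Z_LO || th[7] >= Z_HI) return false;
  if (th[9] < 0.01) return false;
  return true;
}

// truncated normal draw by inverse CDF
double rtnorm(SRng& rng, double m, double s, double lo, double hi) {
  double plo = R::pnorm(lo, m, s, 1, 0), phi = R::pnorm(hi, m, s, 1, 0);
  if (phi - plo < 1e-12) return clampd(m, lo, hi);
  double u = plo + rng.unif() * (phi - plo);
  u = clampd(u, 1e-12, 1.0 - 1e-12);
  return R::qnorm(u, m, s, 1, 0);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".hddm_chain_cpp")]]
List hddm_chain_cpp(NumericVector rt, IntegerVector choice, NumericVector dm,
                    NumericVector ds, IntegerVector stage, IntegerVector subj,
                    int n_subj, LogicalVector active, int n_iter, int warmup,
                    double seed,
                    NumericVector prior_mean, NumericVector prior_sd,
                    NumericVector lower, NumericVector upper,
                    double sigma_prior_sd) {
  int n_trial = rt.size();
  SRng rng((uint64_t)seed);

  std::vector<std::vector<int>> idx(n_subj);
  for (int i = 0; i < n_trial; ++i) idx[subj[i]].push_back(i);
  std::vector<double> min_rt(n_subj, R_PosInf);
  for (int i = 0; i < n_trial; ++i)
    if (rt[i] < min_rt[subj[i]]) min_rt[subj[i]] = rt[i];

  // initial values, lightly jittered per chain
  std::vector<std::vector<double>> th(n_subj, std::vector<double>(NPAR, 0.0));
  for (int s = 0; s < n_subj; ++s) {
    th[s][0] = 0.0 + 0.1 * rng.norm();
    th[s][1] = active[1] ? 0.2 + 0.05 * rng.norm() : 0.0;
    th[s][2] = active[2] ? -0.2 + 0.05 * rng.norm() : 0.0;
    th[s][3] = 0.0;
    th[s][4] = 0.0;
    th[s][5] = 1.5 + 0.1 * std::fabs(rng.norm());
    th[s][6] = 0.0;
    th[s][7] = 0.5 + 0.02 * rng.norm();
    th[s][8] = 0.0;
    th[s][9] = std::min(0.5 * min_rt[s], 0.5) * (0.9 + 0.05 * rng.unif());
  }

  std::vector<double> mu(NPAR, 0.0), sig(NPAR, 0.5);
  for (int k = 0; k < NPAR; ++k) {
    double acc = 0.0;
    for (int s = 0; s < n_subj; ++s) acc += th[s][k];
    mu[k] = acc / n_subj;
    sig[k] = 0.3;
  }

  std::vector<double> ll(n_subj);
  for (int s = 0; s < n_subj; ++s)
    ll[s] = subj_loglik(th[s].data(), rt, choice, dm, ds, stage, idx[s]);

  // adaptive proposal scales
  std::vector<std::vector<double>> step(n_subj, std::vector<double>(NPAR, 0.1));
  std::vector<std::vector<int>> acc_ct(n_subj, std::vector<int>(NPAR, 0));
  std::vector<double> sig_step(NPAR, 0.3);
  std::vector<int> sig_acc(NPAR, 0);
  std::vector<double> tr_step(NPAR, 0.05);
  std::vector<int> tr_acc(NPAR, 0);
  std::vector<double> sc_step(NPAR, 0.3);
  std::vector<int> sc_acc(NPAR, 0);
  const int ADAPT_WIN = 25;

  int n_save = n_iter - warmup;
  std::vector<int> act;
  for (int k = 0; k < NPAR; ++k) if (active[k]) act.push_back(k);
  int n_act = act.size();

  NumericMatrix group_draws(n_save, 2 * n_act);
  NumericMatrix subj_draws(n_save, n_subj * n_act);
  NumericVector deviance(n_save);

  for (int it = 0; it < n_iter; ++it) {
    // participant-level componentwise Metropolis
    for (int s = 0; s < n_subj; ++s) {
      for (int kk = 0; kk < n_act; ++kk) {
        int k = act[kk];
        double cur = th[s][k];
        double prop = cur + step[s][k] * rng.norm();
        th[s][k] = prop;
        bool ok = valid_theta(th[s].data()) && prop > lower[k] &&
                  prop < upper[k];
        if (ok) {
          double llp = subj_loglik(th[s].data(), rt, choice, dm, ds, stage,
                                   idx[s]);
          double lr = llp - ll[s] +
                      R::dnorm(prop, mu[k], sig[k], 1) -
                      R::dnorm(cur, mu[k], sig[k], 1);
          if (R_finite(llp) && std::log(rng.unif()) < lr) {
            ll[s] = llp;
            acc_ct[s][k]++;
            continue;
          }
        }
        th[s][k] = cur;  // reject
      }
    }

    // group-level updates for active parameters
    for (int kk = 0; kk < n_act; ++kk) {
      int k = act[kk];
      // conjugate (truncated) normal for the group mean
      double sum = 0.0;
      for (int s = 0; s < n_subj; ++s) sum += th[s][k];
      double prec = 1.0 / (prior_sd[k] * prior_sd[k]) +
                    n_subj / (sig[k] * sig[k]);
      double m = (prior_mean[k] / (prior_sd[k] * prior_sd[k]) +
                  sum / (sig[k] * sig[k])) / prec;
      mu[k] = rtnorm(rng, m, 1.0 / std::sqrt(prec), lower[k], upper[k]);

      // log-scale random walk for the group sd, half-normal prior
      double lcur = std::log(sig[k]);
      double lprop = lcur + sig_step[k] * rng.norm();
      double sp = std::exp(lprop);
      double lp = 0.0, lc = 0.0;
      for (int s = 0; s < n_subj; ++s) {
        lp += R::dnorm(th[s][k], mu[k], sp, 1);
        lc += R::dnorm(th[s][k], mu[k], sig[k], 1);
      }
      lp += -sp * sp / (2.0 * sigma_prior_sd * sigma_prior_sd) + lprop;
      lc += -sig[k] * sig[k] / (2.0 * sigma_prior_sd * sigma_prior_sd) + lcur;
      if (std::log(rng.unif()) < lp - lc) {
        sig[k] = sp;
        sig_acc[k]++;
      }
    }

    // joint translation: shift the group mean and every participant value
    // together; p(theta | mu, sigma) is invariant, so the ratio involves
    // only the likelihood and the group-mean prior. This breaks the strong
    // coupling between mu_k and the participant-level values that throttles
    // componentwise mixing of the stage deltas.
    for (int kk = 0; kk < n_act; ++kk) {
      int k = act[kk];
      double eps = tr_step[k] * rng.norm();
      double mup = mu[k] + eps;
      if (mup <= lower[k] || mup >= upper[k]) continue;
      bool ok = true;
      for (int s = 0; s < n_subj; ++s) th[s][k] += eps;
      for (int s = 0; s < n_subj; ++s) {
        if (th[s][k] <= lower[k] || th[s][k] >= upper[k] ||
            !valid_theta(th[s].data())) {
          ok = false;
          break;
        }
      }
      if (ok) {
        double lr = R::dnorm(mup, prior_mean[k], prior_sd[k], 1) -
                    R::dnorm(mu[k], prior_mean[k], prior_sd[k], 1);
        std::vector<double> llp(n_subj);
        for (int s = 0; s < n_subj; ++s) {
          llp[s] = subj_loglik(th[s].data(), rt, choice, dm, ds, stage,
                               idx[s]);
          lr += llp[s] - ll[s];
        }
        if (R_finite(lr) && std::log(rng.unif()) < lr) {
          mu[k] = mup;
          for (int s = 0; s < n_subj; ++s) ll[s] = llp[s];
          tr_acc[k]++;
          continue;
        }
      }
      for (int s = 0; s < n_subj; ++s) th[s][k] -= eps;  // undo
    }

    // joint scale: expand or contract the participant residuals together
    // with the group sd (sigma' = c sigma, theta'_i = mu + c (theta_i -
    // mu), c = exp(eps)). The group-normal terms cancel against the
    // Jacobian up to a factor c, so the ratio is likelihood + sigma prior
    // + eps. This walks the narrow neck of the funnel when sigma is small.
    for (int kk = 0; kk < n_act; ++kk) {
      int k = act[kk];
      double eps = sc_step[k] * rng.norm();
      double c = std::exp(eps);
      double sp = sig[k] * c;
      bool ok = true;
      for (int s = 0; s < n_subj; ++s) {
        th[s][k] = mu[k] + c * (th[s][k] - mu[k]);
      }
      for (int s = 0; s < n_subj; ++s) {
        if (th[s][k] <= lower[k] || th[s][k] >= upper[k] ||
            !valid_theta(th[s].data())) {
          ok = false;
          break;
        }
      }
      if (ok) {
        double lr = eps -
          sp * sp / (2.0 * sigma_prior_sd * sigma_prior_sd) +
          sig[k] * sig[k] / (2.0 * sigma_prior_sd * sigma_prior_sd);
        std::vector<double> llp(n_subj);
        for (int s = 0; s < n_subj; ++s) {
          llp[s] = subj_loglik(th[s].data(), rt, choice, dm, ds, stage,
                               idx[s]);
          lr += llp[s] - ll[s];
        }
        if (R_finite(lr) && std::log(rng.unif()) < lr) {
          sig[k] = sp;
          for (int s = 0; s < n_subj; ++s) ll[s] = llp[s];
          sc_acc[k]++;
          continue;
        }
      }
      for (int s = 0; s < n_subj; ++s) {
        th[s][k] = mu[k] + (th[s][k] - mu[k]) / c;  // undo
      }
    }

    // adapt proposals during warmup
    if (it < warmup && (it + 1) % ADAPT_WIN == 0) {
      for (int s = 0; s < n_subj; ++s)
        for (int kk = 0; kk < n_act; ++kk) {
          int k = act[kk];
          double rate = (double)acc_ct[s][k] / ADAPT_WIN;
          step[s][k] *= std::exp(0.66 * (rate - 0.44));
          step[s][k] = clampd(step[s][k], 1e-5, 5.0);
          acc_ct[s][k] = 0;
        }
      for (int kk = 0; kk < n_act; ++kk) {
        int k = act[kk];
        double rate = (double)sig_acc[k] / ADAPT_WIN;
        sig_step[k] *= std::exp(0.66 * (rate - 0.44));
        sig_step[k] = clampd(sig_step[k], 1e-4, 5.0);
        sig_acc[k] = 0;
        double trate = (double)tr_acc[k] / ADAPT_WIN;
        tr_step[k] *= std::exp(0.66 * (trate - 0.25));
        tr_step[k] = clampd(tr_step[k], 1e-5, 5.0);
        tr_acc[k] = 0;
        double scrate = (double)sc_acc[k] / ADAPT_WIN;
        sc_step[k] *= std::exp(0.66 * (scrate - 0.25));
        sc_step[k] = clampd(sc_step[k], 1e-4, 5.0);
        sc_acc[k] = 0;
      }
    }

    if (it >= warmup) {
      int r = it - warmup;
      double dev = 0.0;
      for (int s = 0; s < n_subj; ++s) dev += ll[s];
      deviance[r] = -2.0 * dev;
      for (int kk = 0; kk < n_act; ++kk) {
        group_draws(r, kk) = mu[act[kk]];
        group_draws(r, n_act + kk) = sig[act[kk]];
        for (int s = 0; s < n_subj; ++s)
          subj_draws(r, kk * n_subj + s) = th[s][act[kk]];
      }
    }
  }

  return List::create(_["group"] = group_draws, _["subj"] = subj_draws,
                      _["deviance"] = deviance, _["active"] = act);
}

//' @noRd
// [[Rcpp::export(name = ".hddm_deviance_cpp")]]
double hddm_deviance_cpp(NumericVector rt, IntegerVector choice,
                         NumericVector dm, NumericVector ds,
                         IntegerVector stage, IntegerVector subj, int n_subj,
                         NumericMatrix theta) {
  // deviance of the full data set at fixed participant parameters
  // theta: n_subj x 10 in the canonical layout
  std::vector<std::vector<int>> idx(n_subj);
  for (int i = 0; i < rt.size(); ++i) idx[subj[i]].push_back(i);
  double dev = 0.0;
  for (int s = 0; s < n_subj; ++s) {
    std::vector<double> th(NPAR);
    for (int k = 0; k < NPAR; ++k) th[k] = theta(s, k);
    dev += subj_loglik(th.data(), rt, choice, dm, ds, stage, idx[s]);
  }
  return -2.0 * dev;
}
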