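#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wiener first-passage-time density
//
// ftt01w(): density of first passage through the LOWER boundary at
// standardized decision time tt = t / alpha^2 for a unit-diffusion Wiener
// process with zero drift, boundary separation 1 and relative start w.
// Two series expansions are available (small-time and large-time); the one
// needing fewer terms for the requested absolute error is selected per
// evaluation.
// ---------------------------------------------------------------------------
static double ftt01w(double tt, double w, double err) {
  double kl, ks, p = 0.0;

  // number of terms for the large-time series
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  // number of terms for the small-time series
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }

  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double q = w + 2.0 * k;
      p += q * std::exp(-q * q / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k)
      p += k * std::exp(-(double)k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    p *= M_PI;
  }
  return p;
}

// Signed-rt log density. Positive rt = upper boundary; the upper-boundary
// density is the lower-boundary kernel after the reflection v -> -v,
// z -> 1 - z. z is the relative starting point (fraction of alpha measured
// from the lower boundary).
static double wfpt_ld(double rt, double v, double alpha, double tau, double z,
                      double err) {
  double t = std::fabs(rt) - tau;
  if (!(t > 0.0)) return R_NegInf;
  double w, vv;
  if (rt > 0.0) { w = 1.0 - z; vv = -v; }
  else          { w = z;       vv = v;  }
  double tt = t / (alpha * alpha);
  double f = ftt01w(tt, w, err);
  if (!(f > 0.0)) return R_NegInf;
  return std::log(f) - vv * alpha * w - vv * vv * t / 2.0 -
         2.0 * std::log(alpha);
}

//' @noRd
// [[Rcpp::export]]
NumericVector wfpt_logdensity_cpp(NumericVector rt, NumericVector v,
                                  double alpha, double tau, double z,
                                  double err) {
  R_xlen_t n = rt.size();
  bool vscalar = (v.size() == 1);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = wfpt_ld(rt[i], vscalar ? v[0] : v[i], alpha, tau, z, err);
  return out;
}

// ---------------------------------------------------------------------------
// Per-subject log-likelihoods for the four models.
// model codes: 1 softmax, 2 ddm0, 3 ddml, 4 ddms
// params: one row per subject; column layout per model (see R wrappers).
// subj: 0-based subject index per trial; rt signed (+ = LL choice).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector loglik_subjects_cpp(int model, IntegerVector subj,
                                  NumericVector rt, NumericVector amount,
                                  NumericVector delay, NumericMatrix params,
                                  double ss_amount, double err) {
  int nsub = params.nrow();
  NumericVector out(nsub);
  R_xlen_t n = rt.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int s = subj[i];
    double ll;
    if (model == 1) {
      double logk = params(s, 0), beta = params(s, 1);
      double sv = amount[i] / (1.0 + std::exp(logk) * delay[i]);
      double x = beta * (sv - ss_amount);   // log-odds of choosing LL
      // overflow-safe log p and log(1-p)
      double lp, lq;
      if (x > 0) { lp = -std::log1p(std::exp(-x)); lq = -x + lp; }
      else       { lq = -std::log1p(std::exp(x));  lp = x + lq;  }
      ll = (rt[i] > 0.0) ? lp : lq;
    } else if (model == 2) {
      ll = wfpt_ld(rt[i], params(s, 0), params(s, 1), params(s, 2),
                   params(s, 3), err);
    } else if (model == 3) {
      double logk = params(s, 0), vcoef = params(s, 1);
      double sv = amount[i] / (1.0 + std::exp(logk) * delay[i]);
      double vt = vcoef * (sv - ss_amount);
      ll = wfpt_ld(rt[i], vt, params(s, 2), params(s, 3), params(s, 4), err);
    } else {
      double logk = params(s, 0), vcoef = params(s, 1), vmax = params(s, 2);
      double sv = amount[i] / (1.0 + std::exp(logk) * delay[i]);
      double m = vcoef * (sv - ss_amount);
      double vt = 2.0 * vmax / (1.0 + std::exp(-m)) - vmax;
      ll = wfpt_ld(rt[i], vt, params(s, 3), params(s, 4), params(s, 5), err);
    }
    out[s] += ll;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Self-contained RNG: xoshiro256++ seeded through splitmix64, with a
// Marsaglia-Tsang ziggurat for normal deviates. R's RNG would dominate the
// cost of the 1e6-path Euler oracle, so the simulator keeps its own stream;
// reproducibility comes from the integer seed passed in from R.
// ---------------------------------------------------------------------------
namespace ddmrng {

static inline uint64_t rotl(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// 128-level ziggurat tables for the standard normal (built once)
static double zig_x[129], zig_y[128];
static uint32_t zig_k[128];
static bool zig_ready = false;

static void zig_init() {
  const double r = 3.442619855899;
  const double v = 9.91256303526217e-3;
  double f = std::exp(-0.5 * r * r);
  zig_x[0] = v / f; zig_x[1] = r;
  zig_x[128] = 0.0;
  for (int i = 2; i < 128; ++i) {
    zig_x[i] = std::sqrt(-2.0 * std::log(v / zig_x[i - 1] +
                                         std::exp(-0.5 * zig_x[i - 1] * zig_x[i - 1])));
  }
  for (int i = 0; i < 128; ++i) {
    zig_y[i] = std::exp(-0.5 * zig_x[i + 1] * zig_x[i + 1]);
    zig_k[i] = (uint32_t)((zig_x[i + 1] / zig_x[i]) * 4294967296.0);
  }
  zig_ready = true;
}

static inline double znorm(Xoshiro &g) {
  for (;;) {
    uint64_t u = g.next();
    uint32_t iu = (uint32_t)u;
    int idx = (int)((u >> 32) & 127);
    double sign = ((u >> 40) & 1) ? 1.0 : -1.0;
    double x = (iu * 2.3283064365386963e-10) * zig_x[idx];
    if (iu < zig_k[idx]) return sign * x;
    if (idx == 0) {  // tail
      const double r = 3.442619855899;
      double xx, yy;
      do {
        xx = -std::log(g.unif()) / r;
        yy = -std::log(g.unif());
      } while (yy + yy < xx * xx);
      return sign * (r + xx);
    }
    double y = zig_y[idx - 1] + g.unif() * (zig_y[idx] - zig_y[idx - 1]);
    if (y < std::exp(-0.5 * x * x)) return sign * x;
  }
}

}  // namespace ddmrng

// Euler-Maruyama simulation of first passage (unit diffusion coefficient).
// Returns signed RTs (hitting time + tau, sign = boundary; + = upper) and
// the number of paths that had to be resampled for not terminating by tmax.
// Four paths are advanced in an interleaved fashion: their updates are
// mutually independent, which keeps the floating-point pipeline full and
// roughly halves the wall time of large path ensembles.
// [[Rcpp::export]]
List sim_ddm_cpp(int n, NumericVector v, double alpha, double tau, double z,
                 double dt, double tmax, double seed) {
  if (!ddmrng::zig_ready) ddmrng::zig_init();
  ddmrng::Xoshiro g((uint64_t)seed);
  const bool vscalar = (v.size() == 1);
  NumericVector rt(n);
  int resampled = 0;
  const double sdt = std::sqrt(dt);
  const long maxsteps = (long)std::ceil(tmax / dt);
  const double x0 = z * alpha;
  const int L = 4;
  double x[L], vd[L];
  long st[L];
  int tr[L];
  int next_trial = 0, done = 0;
  for (int l = 0; l < L; ++l) {
    if (next_trial < n) {
      tr[l] = next_trial++;
      x[l] = x0; st[l] = 0;
      vd[l] = (vscalar ? v[0] : v[tr[l]]) * dt;
    } else tr[l] = -1;
  }
  while (done < n) {
    for (int l = 0; l < L; ++l) {
      if (tr[l] < 0) continue;
      x[l] += vd[l] + sdt * ddmrng::znorm(g);
      ++st[l];
      if (x[l] >= alpha || x[l] <= 0.0 || st[l] >= maxsteps) {
        if (x[l] >= alpha)
          rt[tr[l]] = st[l] * dt + tau;
        else if (x[l] <= 0.0)
          rt[tr[l]] = -(st[l] * dt + tau);
        else {  // timed out: resample the same trial
          ++resampled;
          x[l] = x0; st[l] = 0;
          continue;
        }
        ++done;
        if (next_trial < n) {
          tr[l] = next_trial++;
          x[l] = x0; st[l] = 0;
          vd[l] = (vscalar ? v[0] : v[tr[l]]) * dt;
        } else tr[l] = -1;
      }
    }
  }
  return List::create(_["rt"] = rt, _["n_resampled"] = resampled);
}
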