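#include <Rcpp.h>
#include <cstdint>
#include "rates.h"
using namespace Rcpp;

// Self-contained xoshiro256++ generator (seeded via splitmix64) so that
// stochastic traces are bitwise reproducible from the integer seed alone,
// independent of R's RNG state.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform on (0, 1], safe for log()
  double unif_pos() { return 1.0 - unif(); }
};

}  // namespace

// Exact Gillespie simulation of a population of NK independent channels on a
// sequential birth-death chain, with transition rates refreshed at each dt
// boundary from the commanded voltage (hybrid scheme for time-varying clamp).
//
// model: 0 = five-state n^4 chain (rates (4-k) alpha_n, k beta_n),
//        2 = three-state p2 chain (rates k1, k3 up; k2, k4 down)
// V:     commanded voltage (mV) per dt interval
// p_init: stationary occupancy probabilities used to draw the initial counts
//
// Returns an nt x S integer matrix of state counts; row i is the population
// at t = i * dt.  Counts are conserved at every event by construction.
// [[Rcpp::export]]
IntegerMatrix gillespie_cpp(int model, NumericVector V, double dt, int NK,
                            double A, double B, NumericVector p_init,
                            double seed1, double seed2) {
  const int nt = V.size();
  const int S = (model == 2) ? 3 : 5;
  if (p_init.size() != S) stop("p_init has wrong length for this model");
  if (NK < 1) stop("NK must be a positive integer");

  Xoshiro rng(static_cast<uint64_t>(seed1) * 0x100000000ULL +
              static_cast<uint64_t>(seed2));

  // initial counts: one categorical draw per channel from p_init
  std::vector<double> cum(S);
  double acc = 0.0;
  for (int k = 0; k < S; ++k) { acc += p_init[k]; cum[k] = acc; }
  if (std::abs(acc - 1.0) > 1e-8) stop("p_init must sum to 1");
  std::vector<long> N(S, 0);
  for (int c = 0; c < NK; ++c) {
    const double u = rng.unif() * acc;
    int k = 0;
    while (k < S - 1 && u > cum[k]) ++k;
    ++N[k];
  }

  IntegerMatrix out(nt, S);
  double upr[4], dnr[4];  // per-channel rates for s -> s+1 and s+1 -> s

  for (int i = 0; i < nt; ++i) {
    for (int k = 0; k < S; ++k) out(i, k) = static_cast<int>(N[k]);
    if (i == nt - 1) break;

    const double v = V[i];
    if (model == 2) {
      upr[0] = A * alpha_n(v); upr[1] = alpha_n(v);
      dnr[0] = beta_n(v);      dnr[1] = B * beta_n(v);
    } else {
      const double an = alpha_n(v), bn = beta_n(v);
      for (int s = 0; s < 4; ++s) {
        upr[s] = (4 - s) * an;
        dnr[s] = (s + 1) * bn;
      }
    }

    double rem = dt;
    for (;;) {
      double flow[8], tot = 0.0;
      const int nf = S - 1;
      for (int s = 0; s < nf; ++s) {
        flow[s] = N[s] * upr[s];
        flow[nf + s] = N[s + 1] * dnr[s];
        tot += flow[s] + flow[nf + s];
      }
      if (tot <= 0.0) break;
      const double wait = -std::log(rng.unif_pos()) / tot;
      if (wait >= rem) break;
      rem -= wait;
      double u = rng.unif() * tot;
      int j = 0;
      while (j < 2 * nf - 1 && u > flow[j]) { u -= flow[j]; ++j; }
      if (j < nf) { --N[j]; ++N[j + 1]; }
      else        { --N[j - nf + 1]; ++N[j - nf]; }
      if (N[j < nf ? j : j - nf + 1] < 0)
        stop("internal error: negative channel count");
    }
  }
  return out;
}
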