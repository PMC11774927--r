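#include <Rcpp.h>
#include "rates.h"
using namespace Rcpp;

// Forward-Euler integration of gating/occupancy kinetics under voltage clamp.
//
// model: 0 = "n4" (state n), 1 = "hh" (states n, m, h),
//        2 = "p2" (states p1, p2; reduced form of the 3-state chain)
// V:     commanded membrane potential (mV) sampled on the dt grid; rates for
//        the step [t_i, t_i + dt) are evaluated at V[i]
// init:  initial state vector
// tol:   admissible excursion of any state outside [0, 1] before aborting
//
// Returns an nt x nstate matrix; row i is the state at t = i * dt.
// [[Rcpp::export]]
NumericMatrix euler_clamp_cpp(int model, NumericVector V, double dt,
                              NumericVector init, double A, double B,
                              double tol) {
  const int nt = V.size();
  const int ns = (model == 1) ? 3 : (model == 2 ? 2 : 1);
  if (init.size() != ns) stop("init has wrong length for this model");
  NumericMatrix out(nt, ns);
  std::vector<double> s(init.begin(), init.end());

  for (int i = 0; i < nt; ++i) {
    for (int k = 0; k < ns; ++k) {
      if (s[k] < -tol || s[k] > 1.0 + tol)
        stop("state left [0,1] by more than %g at step %d; reduce dt", tol, i);
      out(i, k) = s[k];
    }
    if (i == nt - 1) break;
    const double v = V[i];
    if (model == 2) {
      const double k1 = A * alpha_n(v), k2 = beta_n(v);
      const double k3 = alpha_n(v), k4 = B * beta_n(v);
      const double a11 = -(k1 + k2 + k3), a12 = -k1 + k4;
      const double a21 = k3, a22 = -k4;
      const double p1 = s[0], p2 = s[1];
      s[0] = p1 + dt * (a11 * p1 + a12 * p2 + k1);
      s[1] = p2 + dt * (a21 * p1 + a22 * p2);
    } else {
      const double an = alpha_n(v), bn = beta_n(v);
      s[0] += dt * (an * (1.0 - s[0]) - bn * s[0]);
      if (model == 1) {
        const double am = alpha_m(v), bm = beta_m(v);
        const double ah = alpha_h(v), bh = beta_h(v);
        s[1] += dt * (am * (1.0 - s[1]) - bm * s[1]);
        s[2] += dt * (ah * (1.0 - s[2]) - bh * s[2]);
      }
    }
  }
  return out;
}
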