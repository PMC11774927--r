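#ifndef CHANNELSPECTRA_RATES_H
#define CHANNELSPECTRA_RATES_H

#include <cmath>

// Voltage-dependent gating rate constants (ms^-1), depolarization convention
// (V is displacement from rest, rest = 0 mV).  The 10.001 offset in alpha_n
// regularizes the removable singularity at V = 10 mV and must match the R
// implementation exactly.
inline double alpha_n(double V) {
  return 0.01 * (10.0 - V) / (std::exp((10.001 - V) / 10.0) - 1.0);
}
inline double beta_n(double V) { return 0.125 * std::exp(-V / 80.0); }

inline double alpha_m(double V) {
  return 0.1 * (25.0 - V) / (std::exp((25.0 - V) / 10.0) - 1.0);
}
inline double beta_m(double V) { return 4.0 * std::exp(-V / 18.0); }

inline double alpha_h(double V) { return 0.07 * std::exp(-V / 20.0); }
inline double beta_h(double V) {
  return 1.0 / (std::exp((30.0 - V) / 10.0) + 1.0);
}

#endif
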