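---
title: "Deterministic responses and channel noise of potassium conductance models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic responses and channel noise of potassium conductance models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelspectra)
```

## The models

`channelspectra` studies a voltage-clamped membrane patch carrying a
voltage-gated potassium conductance, in the depolarization convention
(rest = 0 mV, `VK = -12` mV).  Two kinetic descriptions of the same
conductance are implemented side by side.

**The n⁴ gate model.**  The classical squid-axon description: a gating
variable `n` obeys `dn/dt = alpha_n(V)(1 - n) - beta_n(V) n` and the
conductance density is `gK n⁴`.  Microscopically this is a five-state
birth–death chain over the number of open subunits (0–4), with rates
`(4 - k) alpha_n` up and `k beta_n` down; the channel conducts in state 4,
and the stationary occupancy is binomial in `n_inf`.  The rate formulas are
those of the standard parameter table (`hh_gate_rates()`), including the
`10.001` offset in `alpha_n`.  We keep the offset verbatim rather than
substituting the classical form or the analytic limit, because every
downstream number (steady states, time constants, spectra) is defined in
terms of these exact expressions.  The offset displaces rather than
removes the singularity: `alpha_n` is exactly zero at V = 10 and has a
pole at V = 10.001.  None of the working clamp levels touches that sliver,
and the tests that sweep voltage grids step around it.

**The p2 sequential model.**  A three-state chain `0 ⇌ 1 ⇌ 2` with four
independent rate constants tied to the potassium rates by two dimensionless
factors, `k1 = A alpha_n`, `k2 = beta_n`, `k3 = alpha_n`, `k4 = B beta_n`
(`p2_rates()`).  The open probability is the occupancy of state 2 and
involves no exponentiation of a gating variable.  With `A = B = 2` the
chain is exactly the n² model, which anchors a family of structural
identities used throughout the test suite: `p2_inf = n_inf²`, relaxation
times `(tau_n, tau_n/2)`, and a two-Lorentzian noise spectrum with binomial
weights.  The working factors `A = 0.35`, `B = 4` make the p2 model mimic
the n⁴ responses at depolarized potentials; they are the package defaults.

Steady states follow from the stationary reduced system
(`p2_steady_state()`), equivalently the sequential closed form
`k1 k3 / (k2 k4 + k1 k4 + k1 k3)`; the two routes agree to machine
precision and we test that they do.

## Linear analysis

Small perturbations around a clamped level `V0` linearize each gate into a
single-pole transfer `D_x(w) = [dalpha/dV - x0 d(alpha+beta)/dV] /
(iw + alpha + beta)` and give the closed-form admittance density

```
Y = iw Cm + gL + gK [4 n0^3 (V0 - VK) D_n + n0^4]  (+ sodium terms)
```

(`hh_admittance()`), with the p2 analogue built from the rational occupancy
transfer of the reduced two-variable system (`p2_admittance()`).  A single
unit boundary avoids factor-of-2π accidents: public interfaces take
frequencies in Hz, internally `w = 2 pi f / 1000` rad/ms so rates stay in
ms⁻¹, and `uF/cm² × rad/ms = mS/cm²` makes the capacitive term come out in
admittance-density units with no hidden constants.

The closed forms are validated against an independent oracle: drive the
full nonlinear ODE with a single sine of 0.0125 mV, extract the fundamental
Fourier coefficients of current and voltage, and compare the ratio.  The
oracle integrates at `dt = 0.002` ms because the forward-Euler phase error
of a pole at frequency `f` grows like `w dt / 2`, which at 1 kHz and the
production step of 0.01 ms would already be ~3%, larger than the 1%
agreement we require.

`modified_admittance()` drops the capacitive and frequency-independent
terms, leaving only the gating kinetics; its squared magnitude is the
quantity that can be overlaid on fluctuation spectra.

## Quadratic sinusoidal analysis

A multi-sine with integer frequency multipliers `n_k` of a base frequency
`1/T` probes the second-order behavior, provided no second-order
combination (`n_i + n_j`, `|n_i - n_j|`, `2 n_k`) collides with a
first-order frequency or with another combination.  `check_overlap()`
enumerates all combinations exactly in integer arithmetic — frequency
bookkeeping never compares floating-point Hz values — and the canonical
21-multiplier fixture passes this strict check.

Random overlap-free sets are built incrementally
(`generate_nonoverlapping_set()`): candidates are added one at a time and
rejected if they create any collision, restarting when a slot exhausts its
budget.  We chose this over drawing whole sets and rejecting because the
acceptance probability of a uniform 21-subset of 1..1000 is astronomically
small (hundreds of birthday collisions among ~440 combination values in a
~2000-slot range), whereas the incremental construction finds a valid set
in milliseconds and is deterministic given the seed.

`estimate_qsa()` identifies the decomposition `y = y0 + y1 + y2` from one
full period of the response after a transient skip: linear coefficients
`l_k` as ratios of Fourier coefficients at the stimulus bins, quadratic
coefficients from the second-order bins, assembled into the Hermitian
matrix `Q[i, j] = b_{-i, j}`.  Conventions the estimator fixes:

* only `b_{i,j} + b_{j,i}` is identifiable from one output bin, so the
  symmetric convention `b_{i,j} = b_{j,i}` splits each measured bin
  equally;
* `b_{-k,k} = 0` and all DC goes to `y0`; the steady-state response at
  `V0` is subtracted first, so `y0` is the stimulus-induced DC shift only;
* one full period, no windowing, no zero-padding — all frequencies are
  exact FFT bins by construction;
* the record may be circularly shifted: the stimulus window is re-created
  over the same absolute times, and all coefficient ratios are invariant
  under a common time shift.

The estimator is checked against closed forms (a pure squarer has
`b ≡ 1`, a linear filter has `Q ≡ 0`) and by reconstruction: rebuilding the
waveform from `(y0, L, Q)` reproduces the 0.25 mV n⁴ response with a
relative RMS residual below 10⁻³, which bounds third-order leakage at the
default amplitudes.  Component amplitudes default to 0.25 mV for
deterministic work and 1–4 mV for stochastic work, where the quadratic
response must overcome the channel noise; phases are drawn from `[0, π]`
as in the reference parameter table (a flag allows the conventional
`[0, 2π]`).

Power spectra of a single trial (`single_trial_spectra()`) read the output
bins directly: `S_L` at fundamentals, `S_D` at doubled frequencies, `S_P`
and `S_M` at sums and differences, plus the column mean square
`S_R(w_j) = (1/2N) sum_i |Q_{i,j} x_i* x_j|²`.  Averaging over trials with
different random frequency sets (`accumulate_spectra()`) merges the
frequency sets and divides by the per-frequency redundancy counts.  `S_L`
and `S_D` depend only on the frequency (not the phases), so their averages
are exact; `S_P`, `S_M`, `S_R` mix contributions from different source
pairs and converge in the Monte-Carlo sense.

## Stochastic simulation and noise spectra

`simulate_markov()` runs an exact Gillespie simulation of the channel
population, tracking aggregate state counts rather than individual
channels, so the cost scales with the number of transition events.  For a
time-varying clamp the rates are frozen within each `dt = 0.01` ms interval
at the commanded voltage — with per-channel exit rates below 1 ms⁻¹ and
stimulus content at or below ~2 kHz, the frozen-rate error is negligible,
and a guard rejects steps with `max exit rate × dt ≥ 0.1`.  The initial
state is drawn from the stationary distribution and a 50 ms burn-in is
discarded.  The simulator uses its own xoshiro256++ generator seeded from
the user's integer, so identical seeds give bitwise identical traces
regardless of R's RNG state.  The inner loop is compiled (Rcpp), which is
what makes the large-area conditions (up to 9×10⁵ channels, ~10⁹ events)
feasible.

The open-channel count converts to current through the single-channel
conductance `gamma_K = gK × area / N_K` (20 pS at the default density
18 µm⁻² and area 500 µm²), `I_K = open × gamma_K (V - VK)`.

The analytic references are the Lorentzian spectra obtained from the
stationary autocovariance of the open indicator: four Lorentzians with
corner frequencies `q / tau_n` and binomial weights for the n⁴ chain
(`n4_psd()`), two Lorentzians at the eigenvalues of the reduced generator
for the p2 chain (`p2_psd()`), with weights from the open-channel initial
condition.  The one-sided convention is fixed by the variance integral:
`∫₀^∞ S(f) df = N_K i_K² p∞(1 - p∞)`, and `empirical_psd()` uses the
matching periodogram scaling (rectangular window, per-trace mean removal,
arithmetic averaging across iterations; each iteration is one segment).
Records default to 1 s, giving 1 Hz resolution.  Eigenvalues are ordered
slow-mode-first for stable labeling across voltage sweeps; the degenerate
case `T² = 4D` cannot arise for these chains and is flagged as an error
rather than silently merged.

## What the simulations do and do not emulate

The synthetic data are exactly the study conditions of the reference
parameter table: Table-level conductances and reversal potentials, 9000
channels on 500 µm² by default, 0.25 mV (deterministic) or 1–4 mV
(stochastic) stimuli on the 21-frequency fixture, 128 iterations for
spectra (tests use 16 with proportionally widened statistical tolerances;
the experiment registry keeps 128 as the default).  They contain no
measurement noise, no electrode or series-resistance artifacts, no sodium
conductance in the stochastic pathway, and perfectly stationary kinetics —
so passing tests demonstrate internal consistency of the methods and
faithfulness to the model equations, not robustness to the non-idealities
of patch-clamp data.

## Numerical choices

* Forward Euler with `dt = 0.01` ms for production integration (the
  fastest rate times `dt` stays below 0.01 over the working range); the
  admittance oracle uses 0.002 ms as explained above.  First-order
  convergence is verified explicitly by step-halving.
* Transients: deterministic records discard an explicit `skip_ms`
  (default 100 ms ≈ 10–20 relaxation times); stochastic records discard a
  fixed 50 ms burn-in on top of the stationary initial draw.
* `integrate()` with tight relative tolerance for variance integrals; the
  Wiener–Khinchin inversion test uses a dense trapezoid over 0–50 kHz,
  whose truncation error (~10⁻³ relative) sets that test's tolerance.
* The p2 integration uses the reduced `(p1, p2)` system, so probability
  conservation is exact by construction; the equivalence with the full
  three-state generator is tested against an independent Euler integration
  of the 3×3 master equation.
* Overlay normalization: curves are scaled to unity at the lowest shared
  frequency; a least-squares scalar offset in log-power is available as the
  alternative for admittance-vs-spectrum overlays, where the absolute
  level depends on the (constant) stimulus amplitude.

## Known limitations

* The slow-Lorentzian dominance of the n⁴ noise spectrum at strong
  depolarization is a low-frequency statement: the S₁ share of the total
  tends to `w₁ / Σ q w_q` (≈ 0.68 at 55 mV) at high frequency because all
  Lorentzian tails fall as `w⁻²`.  The package therefore quantifies
  dominance at the low-frequency end of the comparison band.
* At 5 mV a 3-significant-figure rounding of `n_inf⁴` gives 0.0246 from
  the exact Table formulas (0.024643); the conventional offset-free
  `alpha_n` rounds to 0.0247.  The difference (0.2%) is far below every
  tolerance used here but is worth knowing when comparing printed digits.
* Sodium-channel stochastic simulation, Langevin/SDE approximations and
  current-clamp operation are out of scope; the admittance supports the
  full model (sodium included), the stochastic and QSA machinery is
  potassium-only.
* `alpha_m` keeps its removable singularity at exactly V = 25 mV; the
  working clamp levels avoid it.
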