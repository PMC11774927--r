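# Shared oracles, independent of the closed-form implementations they check.

# Small-signal admittance by finite differences: drive the full nonlinear ODE
# with a single small sine and take the ratio of fundamental Fourier
# coefficients of current and voltage.  dt is finer than the production
# default so the Euler phase error stays well below the comparison tolerance.
fd_admittance <- function(model, V0, f_Hz, amplitude_mV = 0.0125,
                          dt_ms = 0.002, A = 0.35, B = 4,
                          params = hh_parameters(gNa = 0)) {
  T_ms <- 1000 / f_Hz
  ncyc_tr <- ceiling(120 / T_ms)          # >= 120 ms transient, whole cycles
  nper <- 5
  n <- round((ncyc_tr + nper) * T_ms / dt_ms)
  t <- (seq_len(n) - 1) * dt_ms
  w <- 2 * pi * f_Hz / 1000
  V <- V0 + amplitude_mV * cos(w * t)
  dV <- -amplitude_mV * w * sin(w * t)
  tr <- integrate_voltage_clamp(model, V, dt_ms, params = params,
                                A = A, B = B, dVdt = dV)
  i0 <- ncyc_tr * round(T_ms / dt_ms)
  win <- (i0 + 1):n
  nw <- length(win)
  e <- exp(-2i * pi * nper * (seq_len(nw) - 1) / nw)
  sum(tr$I_total[win] * e) / sum((V[win] - V0) * e)
}

# Independent brute-force overlap enumeration used to cross-check the
# package's checker: every second-order combination value, tagged by its
# unordered source pair.
brute_force_overlap_free <- function(m) {
  vals <- c(outer(m, m, "+")[upper.tri(diag(length(m)))],
            abs(outer(m, m, "-"))[upper.tri(diag(length(m)))],
            2 * m)
  !any(vals %in% m) && !anyDuplicated(vals)
}

# Deterministic QSA run of a model under a given stimulus; returns the
# response (total clamp current density) and the steady-state baseline.
ode_qsa_response <- function(model, V0, spec, dt_ms = 0.01, skip_ms = 100,
                             A = 0.35, B = 4, params = hh_parameters()) {
  dur <- skip_ms + spec$period_s * 1000
  x <- synthesize_multisine(spec, dt_ms, dur, derivative = TRUE)
  tr <- integrate_voltage_clamp(model, V0 + x, dt_ms, params = params,
                                A = A, B = B, dVdt = attr(x, "dxdt"))
  ss <- integrate_voltage_clamp(model, rep(V0, 2), dt_ms, params = params,
                                A = A, B = B)
  list(response = tr$I_total, baseline = ss$I_total[1] - ss$Icap[1])
}

# stimulus frequencies plus all their second-order combinations (Hz, T = 1 s)
stimulus_line_frequencies <- function(multipliers) {
  n <- length(multipliers)
  ut <- upper.tri(diag(n))
  c(multipliers, 2 * multipliers,
    outer(multipliers, multipliers, "+")[ut],
    abs(outer(multipliers, multipliers, "-"))[ut])
}
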