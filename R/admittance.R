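#' Small-signal gating transfer function
#'
#' Frequency-domain response of one gating variable to a small voltage
#' perturbation around the steady state at `V0`:
#' `D_x(w) = [dalpha/dV - x0 d(alpha+beta)/dV] / (iw + alpha + beta)`
#' with `x0 = x_inf(V0)`.  Units are 1/mV, so
#' `gK * 4 n0^3 (V0 - VK) * D_n` is an admittance density.
#'
#' Public frequencies are in Hz; internally `w = 2 pi f / 1000` rad/ms so
#' that the rate constants stay in ms^-1.
#'
#' @param V0 clamp potential (mV), scalar
#' @param gate `"n"`, `"m"` or `"h"`
#' @param f_Hz frequency grid (Hz); negative frequencies are allowed and
#'   give the complex conjugate response
#' @return Complex vector, one element per frequency.
#' @export
gating_transfer <- function(V0, gate, f_Hz) {
  r <- hh_gate_rates(V0, gate)
  w <- 2 * pi * f_Hz / 1000
  (r$dalpha_dV - r$x_inf * (r$dalpha_dV + r$dbeta_dV)) /
    (1i * w + r$alpha + r$beta)
}

linear_response <- function(V0, f_Hz, Y, model, components) {
  structure(data.frame(f_Hz = f_Hz, Re_Y = Re(Y), Im_Y = Im(Y),
                       abs_Z = abs(1 / Y), phase_Z = Arg(1 / Y)),
            Y = Y, Z = 1 / Y, V0 = V0, model = model,
            components = components,
            class = c("linear_response", "data.frame"))
}

#' Closed-form admittance of the Hodgkin-Huxley model
#'
#' Linearized admittance density at a clamped potential `V0`:
#' `Y = iw Cm + gL + gK [4 n0^3 (V0-VK) D_n + n0^4]
#'    + gNa [3 m0^2 h0 (V0-VNa) D_m + m0^3 (V0-VNa) D_h + m0^3 h0]`
#' and impedance `Z = 1/Y`.  Setting `gNa = 0` in `params` isolates the
#' potassium conductance.  `Y` is in mS/cm^2 (the capacitive term uses
#' `w` in rad/ms so that uF/cm^2 x rad/ms = mS/cm^2).
#'
#' @param V0 clamp potential (mV)
#' @param f_Hz frequency grid (Hz)
#' @param params [hh_parameters()]
#' @return A `linear_response` data frame (columns `f_Hz`, `Re_Y`, `Im_Y`,
#'   `abs_Z`, `phase_Z`) carrying the complex `Y`, `Z` and the per-gate
#'   transfer terms as attributes.
#' @examples
#' lr <- hh_admittance(5, 10^seq(0, 3, length.out = 50))
#' which.max(lr$abs_Z)   # impedance resonance
#' @export
hh_admittance <- function(V0, f_Hz, params = hh_parameters()) {
  w <- 2 * pi * f_Hz / 1000
  n0 <- hh_gate_rates(V0, "n")$x_inf
  m0 <- hh_gate_rates(V0, "m")$x_inf
  h0 <- hh_gate_rates(V0, "h")$x_inf
  Dn <- gating_transfer(V0, "n", f_Hz)
  Dm <- gating_transfer(V0, "m", f_Hz)
  Dh <- gating_transfer(V0, "h", f_Hz)
  Y <- 1i * w * params$Cm + params$gL +
    params$gK * (4 * n0^3 * (V0 - params$VK) * Dn + n0^4) +
    params$gNa * (3 * m0^2 * h0 * (V0 - params$VNa) * Dm +
                  m0^3 * (V0 - params$VNa) * Dh + m0^3 * h0)
  if (any(Y == 0)) stop("admittance vanished on the grid")
  linear_response(V0, f_Hz, Y, "hh", list(Dn = Dn, Dm = Dm, Dh = Dh))
}

#' Small-signal occupancy transfer of the p2 model
#'
#' The rational transfer `dp2_hat / dV_hat` of the reduced two-variable p2
#' system, with second-order denominator
#' `(iw - a11)(iw - a22) - a21 a12` and all generator derivatives taken
#' analytically.  Units 1/mV.
#'
#' @inheritParams gating_transfer
#' @param A,B p2 rate factors
#' @return Complex vector over `f_Hz`.
#' @export
p2_transfer <- function(V0, f_Hz, A = 0.35, B = 4) {
  w <- 2 * pi * f_Hz / 1000
  r <- p2_rates(V0, A, B)
  d <- p2_rate_derivatives(V0, A, B)
  ss <- p2_steady_state(V0, A, B)
  num <- r$a21 * (d$da11 * ss$p1_inf + d$da12 * ss$p2_inf -
                    (d$da22 + d$da12)) +
    (1i * w - r$a11) * (d$da21 * ss$p1_inf + d$da22 * ss$p2_inf)
  den <- (1i * w - r$a11) * (1i * w - r$a22) - r$a21 * r$a12
  num / den
}

#' Closed-form admittance of the p2 model
#'
#' `Y = iw Cm + gL + gK [dp2/dV (V0 - VK) + p2_inf]` with the occupancy
#' transfer of [p2_transfer()].  With `A = B = 2` this equals the n^2
#' variant of the Hodgkin-Huxley admittance (replace `n^4 -> n^2`,
#' `4 n^3 -> 2 n`) to machine precision.
#'
#' @inheritParams hh_admittance
#' @param A,B p2 rate factors
#' @return A `linear_response` data frame, as for [hh_admittance()].
#' @export
p2_admittance <- function(V0, f_Hz, params = hh_parameters(),
                          A = 0.35, B = 4) {
  w <- 2 * pi * f_Hz / 1000
  tr <- p2_transfer(V0, f_Hz, A, B)
  p2inf <- p2_steady_state(V0, A, B)$p2_inf
  Y <- 1i * w * params$Cm + params$gL +
    params$gK * (tr * (V0 - params$VK) + p2inf)
  linear_response(V0, f_Hz, Y, "p2", list(dp2_dV = tr))
}

#' Modified admittance for spectrum overlays
#'
#' The gating part of the admittance with neither the capacitive term nor
#' the frequency-independent conductance terms, used to overlay evoked
#' linear kinetics on fluctuation spectra:
#' `Ym = gK 4 n0^3 (V0-VK) D_n` for the n^4 model and the analogous
#' `gK (V0-VK) dp2/dV` for the p2 model.
#'
#' @inheritParams hh_admittance
#' @param model `"n4"` or `"p2"`
#' @param A,B p2 rate factors
#' @return A data frame with columns `f_Hz`, `Re_Ym`, `Im_Ym`, `abs_Ym2`
#'   (squared magnitude), carrying the complex `Ym` as an attribute.
#' @export
modified_admittance <- function(V0, f_Hz, model = c("n4", "p2"),
                                params = hh_parameters(), A = 0.35, B = 4) {
  model <- match.arg(model)
  Ym <- if (model == "n4") {
    n0 <- hh_gate_rates(V0, "n")$x_inf
    params$gK * 4 * n0^3 * (V0 - params$VK) * gating_transfer(V0, "n", f_Hz)
  } else {
    params$gK * (V0 - params$VK) * p2_transfer(V0, f_Hz, A, B)
  }
  structure(data.frame(f_Hz = f_Hz, Re_Ym = Re(Ym), Im_Ym = Im(Ym),
                       abs_Ym2 = abs(Ym)^2),
            Ym = Ym, V0 = V0, model = model)
}
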