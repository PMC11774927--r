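#' Voltage-dependent gating rate constants
#'
#' Evaluates the rate constants alpha(V), beta(V) of one Hodgkin-Huxley gate
#' together with their exact analytic voltage derivatives, the steady state
#' `x_inf = alpha/(alpha + beta)` and the time constant
#' `tau = 1/(alpha + beta)`.  Potentials follow the depolarization convention
#' (rest = 0 mV).  The `10.001` offset in `alpha_n` is kept verbatim as
#' printed in the reference parameter table; note that it displaces rather
#' than removes the singularity, so `alpha_n` has a zero at exactly V = 10
#' and a pole at V = 10.001, a 1-per-mil-mV sliver avoided by every working
#' clamp level.  `alpha_m` retains its classical removable singularity at
#' V = 25 mV.
#'
#' @param V membrane potential (mV), numeric vector, finite
#' @param gate one of `"n"` (potassium activation), `"m"` (sodium
#'   activation), `"h"` (sodium inactivation)
#'
#' @return A list of class `gating_rate_set` with numeric vectors `alpha`,
#'   `beta` (ms^-1), `dalpha_dV`, `dbeta_dV` (ms^-1 mV^-1), `x_inf`
#'   (dimensionless), `tau` (ms), and the `gate` id.
#' @examples
#' r <- hh_gate_rates(5, "n")
#' r$x_inf^4     # ~ 0.0247: potassium open probability at a 5 mV step
#' @export
hh_gate_rates <- function(V, gate = c("n", "m", "h")) {
  gate <- match.arg(gate)
  if (!is.numeric(V) || !all(is.finite(V))) stop("V must be finite numeric")
  if (gate == "n") {
    E <- exp((10.001 - V) / 10)
    alpha <- 0.01 * (10 - V) / (E - 1)
    dalpha <- 0.01 * (-(E - 1) + (10 - V) * E / 10) / (E - 1)^2
    beta <- 0.125 * exp(-V / 80)
    dbeta <- -beta / 80
  } else if (gate == "m") {
    E <- exp((25 - V) / 10)
    alpha <- 0.1 * (25 - V) / (E - 1)
    dalpha <- 0.1 * (-(E - 1) + (25 - V) * E / 10) / (E - 1)^2
    beta <- 4 * exp(-V / 18)
    dbeta <- -beta / 18
  } else {
    alpha <- 0.07 * exp(-V / 20)
    dalpha <- -alpha / 20
    G <- exp((30 - V) / 10)
    beta <- 1 / (G + 1)
    dbeta <- G / (10 * (G + 1)^2)
  }
  tot <- alpha + beta
  structure(list(gate = gate, alpha = alpha, beta = beta,
                 dalpha_dV = dalpha, dbeta_dV = dbeta,
                 x_inf = alpha / tot, tau = 1 / tot),
            class = "gating_rate_set")
}

#' Steady state of all Hodgkin-Huxley gates
#'
#' @param V membrane potential (mV), scalar
#' @return Named vector `c(n = , m = , h = )` of steady-state gate values.
#' @export
hh_steady_state <- function(V) {
  c(n = hh_gate_rates(V, "n")$x_inf,
    m = hh_gate_rates(V, "m")$x_inf,
    h = hh_gate_rates(V, "h")$x_inf)
}
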