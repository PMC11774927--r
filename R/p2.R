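#' Rate constants and generator entries of the p2 model
#'
#' The p2 model is a three-state sequential chain 0 <-> 1 <-> 2 whose open
#' state is state 2.  Its four rate constants are tied to the potassium gate
#' rates by two dimensionless factors: `k1 = A * alpha_n`, `k2 = beta_n`,
#' `k3 = alpha_n`, `k4 = B * beta_n`.  With `A = B = 2` the chain is exactly
#' the n^2 model.  The occupancy dynamics reduce (using p0 + p1 + p2 = 1) to
#' a 2-variable linear system with matrix entries `a11 = -(k1 + k2 + k3)`,
#' `a12 = -k1 + k4`, `a21 = k3`, `a22 = -k4`.
#'
#' @param V membrane potential (mV), numeric vector
#' @param A,B positive dimensionless rate factors (defaults as used for the
#'   potassium-like p2 simulations)
#'
#' @return A list with vectors `k1`..`k4` (ms^-1) and `a11`, `a12`, `a21`,
#'   `a22` (ms^-1).
#' @examples
#' p2_rates(55)$k3   # = alpha_n(55)
#' @export
p2_rates <- function(V, A = 0.35, B = 4) {
  if (!is.numeric(A) || !is.numeric(B) || A <= 0 || B <= 0)
    stop("factors A and B must be positive")
  rn <- hh_gate_rates(V, "n")
  k1 <- A * rn$alpha; k2 <- rn$beta; k3 <- rn$alpha; k4 <- B * rn$beta
  list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
       a11 = -(k1 + k2 + k3), a12 = -k1 + k4, a21 = k3, a22 = -k4)
}

#' Voltage derivatives of the p2 generator entries
#'
#' Analytic derivatives d(aij)/dV obtained from the exact derivatives of the
#' potassium gate rates; used by the closed-form p2 admittance.
#'
#' @inheritParams p2_rates
#' @return A list with vectors `da11`, `da12`, `da21`, `da22`
#'   (ms^-1 mV^-1).
#' @export
p2_rate_derivatives <- function(V, A = 0.35, B = 4) {
  rn <- hh_gate_rates(V, "n")
  dk1 <- A * rn$dalpha_dV; dk2 <- rn$dbeta_dV
  dk3 <- rn$dalpha_dV; dk4 <- B * rn$dbeta_dV
  list(da11 = -(dk1 + dk2 + dk3), da12 = -dk1 + dk4,
       da21 = dk3, da22 = -dk4)
}

#' Steady-state occupancies of the p2 model
#'
#' Solves the stationary reduced system by the 2x2 matrix inverse,
#' `(p1_inf, p2_inf)' = M^-1 (a22 + a12, 0)'`.  The result agrees with the
#' sequential-chain closed form
#' `p2_inf = k1 k3 / (k2 k4 + k1 k4 + k1 k3)` to machine precision.
#'
#' @inheritParams p2_rates
#' @return A list with vectors `p1_inf`, `p2_inf` and `p0_inf`.
#' @examples
#' p2_steady_state(5)$p2_inf    # ~ 0.0297
#' p2_steady_state(55)$p2_inf   # ~ 0.565
#' @export
p2_steady_state <- function(V, A = 0.35, B = 4) {
  r <- p2_rates(V, A, B)
  D <- r$a11 * r$a22 - r$a12 * r$a21
  scale <- pmax(abs(r$a11 * r$a22), abs(r$a12 * r$a21), 1e-300)
  if (any(abs(D) < 1e-12 * scale))
    stop("singular p2 generator (determinant ~ 0) at V = ",
         paste(V[abs(D) < 1e-12 * scale], collapse = ", "))
  p1 <- r$a22 * (r$a22 + r$a12) / D
  p2 <- -r$a21 * (r$a22 + r$a12) / D
  list(p1_inf = p1, p2_inf = p2, p0_inf = 1 - p1 - p2)
}
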