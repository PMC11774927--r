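#' Deterministic voltage-clamp integration
#'
#' Integrates the gating (n^4 or full Hodgkin-Huxley) or occupancy (p2)
#' kinetics by forward Euler with the membrane potential forced to the
#' commanded trajectory, and reports the per-species current densities and
#' the total clamp current `I = Cm dV/dt + IL + IK (+ INa)`.
#'
#' Initial conditions default to the steady state at `V_command[1]`.  The
#' first `10 * max(tau)` of a trace should be treated as transient when the
#' command is not constant; spectral estimators in this package take an
#' explicit `skip_ms` for that purpose.
#'
#' @param model `"n4"` (potassium only), `"hh"` (potassium + sodium + leak),
#'   or `"p2"` (three-state chain, potassium only)
#' @param V_command commanded potential (mV) sampled on the `dt_ms` grid
#' @param dt_ms Euler time step (ms); the default 0.01 keeps the fastest
#'   rate times dt well below 0.01 over the working voltage range
#' @param params [hh_parameters()]
#' @param A,B p2 rate factors (ignored for the gate models)
#' @param init `"steady"` or a numeric state vector (`n` / `c(n,m,h)` /
#'   `c(p1,p2)`)
#' @param dVdt optional analytic derivative of the command (mV/ms); when
#'   absent, central differences are used for the capacitive current
#' @param tol admissible excursion of a state outside `[0, 1]` before the
#'   integration aborts with advice to reduce `dt_ms`
#'
#' @return A data frame of class `state_trace` with columns `time_ms`,
#'   `V_mV`, the state variables, and current densities `IL`, `IK`, `INa`,
#'   `Icap`, `I_total` (uA/cm^2).  Attributes: `model`, `dt_ms`, `params`.
#' @examples
#' tr <- integrate_voltage_clamp("n4", rep(5, 1001), dt_ms = 0.01)
#' tail(tr$IK, 1)   # relaxes towards gK * n_inf(5)^4 * (5 - VK)
#' @export
integrate_voltage_clamp <- function(model = c("n4", "hh", "p2"), V_command,
                                    dt_ms = 0.01, params = hh_parameters(),
                                    A = 0.35, B = 4, init = "steady",
                                    dVdt = NULL, tol = 1e-6) {
  model <- match.arg(model)
  stopifnot(is.numeric(V_command), length(V_command) >= 2, dt_ms > 0)
  if (!all(is.finite(V_command))) stop("V_command must be finite")
  code <- c(n4 = 0L, hh = 1L, p2 = 2L)[[model]]

  if (identical(init, "steady")) {
    v0 <- V_command[1]
    init <- switch(model,
      n4 = hh_gate_rates(v0, "n")$x_inf,
      hh = unname(hh_steady_state(v0)),
      p2 = { ss <- p2_steady_state(v0, A, B); c(ss$p1_inf, ss$p2_inf) })
  }
  states <- euler_clamp_cpp(code, V_command, dt_ms, init, A, B, tol)

  nt <- length(V_command)
  if (is.null(dVdt)) {
    mid <- if (nt > 2)
      (V_command[seq(3, nt)] - V_command[seq(1, nt - 2)]) / 2 else numeric(0)
    dVdt <- c(V_command[2] - V_command[1], mid,
              V_command[nt] - V_command[nt - 1]) / dt_ms
  } else stopifnot(length(dVdt) == nt)

  IL <- params$gL * (V_command - params$VL)
  if (model == "p2") {
    open <- states[, 2]
    df <- data.frame(time_ms = (seq_len(nt) - 1) * dt_ms, V_mV = V_command,
                     p0 = 1 - states[, 1] - states[, 2],
                     p1 = states[, 1], p2 = states[, 2])
  } else {
    open <- states[, 1]^4
    df <- data.frame(time_ms = (seq_len(nt) - 1) * dt_ms, V_mV = V_command,
                     n = states[, 1])
    if (model == "hh") { df$m <- states[, 2]; df$h <- states[, 3] }
  }
  df$IL <- IL
  df$IK <- params$gK * open * (V_command - params$VK)
  df$INa <- if (model == "hh")
    params$gNa * df$m^3 * df$h * (V_command - params$VNa) else 0
  df$Icap <- params$Cm * dVdt
  df$I_total <- df$Icap + df$IL + df$IK + df$INa
  structure(df, model = model, dt_ms = dt_ms, params = params,
            A = A, B = B, class = c("state_trace", "data.frame"))
}

#' Potassium current of a deterministic trace
#'
#' Extracts the potassium current density of a [integrate_voltage_clamp()]
#' trace and, when a membrane area is given, the absolute current with the
#' uA/cm^2 x um^2 -> pA conversion.
#'
#' @param trace a `state_trace`
#' @param area_um2 membrane area (um^2); required for `absolute = TRUE`
#' @param absolute return absolute current in pA instead of density
#' @return Numeric vector: density (uA/cm^2) or absolute current (pA).
#' @export
deterministic_potassium_current <- function(trace, area_um2 = NULL,
                                            absolute = !is.null(area_um2)) {
  stopifnot(inherits(trace, "state_trace"))
  ik <- trace$IK
  if (!absolute) return(ik)
  if (is.null(area_um2))
    stop("area_um2 is required to report absolute current in pA")
  ik * area_um2 * 1e-2   # uA/cm^2 * um^2 = 1e-8 uA = 1e-2 pA
}

#' Write a state trace to CSV with a JSON parameter sidecar
#'
#' @param trace a `state_trace`
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.json`
#' @param seed optional RNG seed to record
#' @return Invisibly, the CSV path.
#' @export
write_state_trace <- function(trace, file, seed = NULL) {
  write.csv(as.data.frame(trace), file, row.names = FALSE)
  meta <- list(model = attr(trace, "model"), dt_ms = attr(trace, "dt_ms"),
               params = unclass(attr(trace, "params")),
               A = attr(trace, "A"), B = attr(trace, "B"), seed = seed)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}
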