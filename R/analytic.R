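#' Analytic autocovariance of the n^4 potassium current
#'
#' Stationary autocovariance of the total fluctuating current of `N_K`
#' independent n^4 channels,
#' `C_IK(t) = N_K i_K^2 n^4 sum_{q=1..4} C(4,q) n^(4-q) (1-n)^q
#' e^{-q t / tau_n}` with `n = n_inf(V0)`; at lag 0 this is the binomial
#' variance `N_K i_K^2 n^4 (1 - n^4)`.
#'
#' @param lag_s time lag (s), nonnegative, vectorized
#' @param V0 clamp potential (mV)
#' @param population a [channel_population()]
#' @return Autocovariance (pA^2).
#' @export
n4_autocovariance <- function(lag_s, V0, population = channel_population()) {
  stopifnot(all(lag_s >= 0))
  r <- hh_gate_rates(V0, "n")
  n <- r$x_inf
  tau_s <- r$tau * 1e-3
  iK <- single_channel_current(population, V0)
  terms <- sapply(1:4, function(q)
    choose(4, q) * n^(4 - q) * (1 - n)^q * exp(-q * lag_s / tau_s))
  population$N_K * iK^2 * n^4 * rowSums(matrix(terms, nrow = length(lag_s)))
}

#' Four-Lorentzian fluctuation spectrum of the n^4 model
#'
#' One-sided power spectral density of the spontaneous potassium current
#' noise, `S_IK(w) = 4 N_K i_K^2 n^4 sum_q C(4,q) n^(4-q) (1-n)^q
#' q tau_n / (q^2 + w^2 tau_n^2)` with `w = 2 pi f` and `tau_n` in seconds:
#' four Lorentzians with corner frequencies `w_q = q / tau_n`.  The
#' one-sided convention satisfies
#' `integral S_IK df = C_IK(0)` over positive frequencies.
#'
#' @param f_Hz frequency grid (Hz)
#' @inheritParams n4_autocovariance
#' @return Data frame `f_Hz`, `S_total`, `S1`..`S4` (pA^2/Hz); attribute
#'   `corner_Hz` holds the four corner frequencies in Hz.
#' @export
n4_psd <- function(f_Hz, V0, population = channel_population()) {
  r <- hh_gate_rates(V0, "n")
  n <- r$x_inf
  tau_s <- r$tau * 1e-3
  iK <- single_channel_current(population, V0)
  w <- 2 * pi * f_Hz
  pref <- 4 * population$N_K * iK^2 * n^4
  comps <- sapply(1:4, function(q)
    pref * choose(4, q) * n^(4 - q) * (1 - n)^q *
      q * tau_s / (q^2 + w^2 * tau_s^2))
  comps <- matrix(comps, nrow = length(f_Hz))
  colnames(comps) <- paste0("S", 1:4)
  structure(data.frame(f_Hz = f_Hz, S_total = rowSums(comps), comps),
            corner_Hz = (1:4) / tau_s / (2 * pi), V0 = V0, model = "n4")
}

#' Eigensystem of the p2 relaxation matrix
#'
#' Eigenvalues and autocovariance weights of the reduced 2x2 generator of
#' the p2 chain at a clamp level.  `lambda1 >= lambda2` (slow mode first),
#' both negative in the working range; time constants `tau_q = -1/lambda_q`.
#' The weights follow from the open-channel initial condition
#' `(p0, p1, p2) = (0, 0, 1)`:
#' `c1 = [(lambda2 - a22)(1 - p2_inf) + a21 p1_inf] / (lambda2 - lambda1)`,
#' `c2 = 1 - p2_inf - c1`, so `c1 + c2 = 1 - p2_inf`.
#'
#' @param V0 clamp potential (mV)
#' @param A,B p2 rate factors
#' @return List of class `p2_eigensystem`: `trace_T`, `det_D`, `lambda1`,
#'   `lambda2` (ms^-1), `tau1_ms`, `tau2_ms`, eigenvectors `v1`, `v2`,
#'   weights `c1`, `c2`, and the steady state.
#' @export
p2_eigensystem <- function(V0, A = 0.35, B = 4) {
  r <- p2_rates(V0, A, B)
  ss <- p2_steady_state(V0, A, B)
  Tr <- r$a11 + r$a22
  D <- r$a11 * r$a22 - r$a12 * r$a21
  disc <- Tr^2 - 4 * D
  if (disc < 0)
    stop("complex p2 eigenvalues (T = ", signif(Tr, 6), ", D = ",
         signif(D, 6), "): outside the sequential-chain working range")
  if (disc == 0)
    stop("degenerate p2 eigenvalues (T^2 = 4D); the confluent limit is not ",
         "implemented")
  sq <- sqrt(disc)
  l1 <- (Tr + sq) / 2; l2 <- (Tr - sq) / 2
  c1 <- ((l2 - r$a22) * (1 - ss$p2_inf) + r$a21 * ss$p1_inf) / (l2 - l1)
  structure(list(trace_T = Tr, det_D = D, lambda1 = l1, lambda2 = l2,
                 tau1_ms = -1 / l1, tau2_ms = -1 / l2,
                 v1 = c((l1 - r$a22) / r$a21, 1),
                 v2 = c((l2 - r$a22) / r$a21, 1),
                 c1 = c1, c2 = 1 - ss$p2_inf - c1,
                 p1_inf = ss$p1_inf, p2_inf = ss$p2_inf,
                 V0 = V0, A = A, B = B),
            class = "p2_eigensystem")
}

#' Analytic autocovariance of the p2 current
#'
#' `C_IK(t) = N_K i_K^2 p2_inf (c1 e^{lambda1 t} + c2 e^{lambda2 t})`; at
#' lag 0 this is `N_K i_K^2 p2_inf (1 - p2_inf)`.
#'
#' @inheritParams n4_autocovariance
#' @param A,B p2 rate factors
#' @return Autocovariance (pA^2).
#' @export
p2_autocovariance <- function(lag_s, V0, population = channel_population(),
                              A = 0.35, B = 4) {
  stopifnot(all(lag_s >= 0))
  es <- p2_eigensystem(V0, A, B)
  iK <- single_channel_current(population, V0)
  lag_ms <- lag_s * 1e3
  population$N_K * iK^2 * es$p2_inf *
    (es$c1 * exp(es$lambda1 * lag_ms) + es$c2 * exp(es$lambda2 * lag_ms))
}

#' Two-Lorentzian fluctuation spectrum of the p2 model
#'
#' One-sided power spectral density
#' `S_IK(w) = 4 N_K i_K^2 p2_inf [c1 tau1 / (1 + w^2 tau1^2) +
#' c2 tau2 / (1 + w^2 tau2^2)]` with the time constants in seconds and
#' `w = 2 pi f`; corner frequencies `1/tau1` and `1/tau2`.
#'
#' @inheritParams n4_psd
#' @param A,B p2 rate factors
#' @return Data frame `f_Hz`, `S_total`, `S1`, `S2` (pA^2/Hz); attribute
#'   `corner_Hz`.
#' @export
p2_psd <- function(f_Hz, V0, population = channel_population(),
                   A = 0.35, B = 4) {
  es <- p2_eigensystem(V0, A, B)
  iK <- single_channel_current(population, V0)
  w <- 2 * pi * f_Hz
  t1 <- es$tau1_ms * 1e-3; t2 <- es$tau2_ms * 1e-3
  pref <- 4 * population$N_K * iK^2 * es$p2_inf
  S1 <- pref * es$c1 * t1 / (1 + w^2 * t1^2)
  S2 <- pref * es$c2 * t2 / (1 + w^2 * t2^2)
  structure(data.frame(f_Hz = f_Hz, S_total = S1 + S2, S1 = S1, S2 = S2),
            corner_Hz = c(1 / t1, 1 / t2) / (2 * pi), V0 = V0, model = "p2")
}
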