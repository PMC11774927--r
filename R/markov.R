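#' Stationary state-occupancy distribution of a channel chain
#'
#' Binomial over the five states of the n^4 chain (`p_k = C(4,k) n^k
#' (1-n)^(4-k)` with `n = n_inf(V)`), or the stationary solution of the
#' three-state p2 chain.
#'
#' @param model `"n4"` or `"p2"`
#' @param V membrane potential (mV), scalar
#' @param A,B p2 rate factors
#' @return Probability vector over the chain states (closed ... open).
#' @export
stationary_distribution <- function(model = c("n4", "p2"), V,
                                    A = 0.35, B = 4) {
  model <- match.arg(model)
  if (model == "n4") {
    n <- hh_gate_rates(V, "n")$x_inf
    stats::dbinom(0:4, 4, n)
  } else {
    ss <- p2_steady_state(V, A, B)
    c(ss$p0_inf, ss$p1_inf, ss$p2_inf)
  }
}

#' Stochastic Markov simulation of a channel population
#'
#' Exact Gillespie simulation of `N_K` independent channels on the
#' five-state n^4 chain (rates `(4-k) alpha_n`, `k beta_n`) or the
#' three-state p2 chain (rates `k1..k4`), under a constant or time-varying
#' voltage clamp.  Transition rates are refreshed at each `dt_ms` boundary
#' from the commanded voltage and frozen within the interval, where the
#' algorithm is event-exact; state counts are sampled onto the uniform grid.
#' Aggregate counts (not individual channels) are simulated, so the cost
#' scales with the number of transition events.
#'
#' The initial state is drawn from the stationary distribution at
#' `V_command[1]` and a burn-in of `burn_ms` (simulated at constant
#' `V_command[1]`) is discarded.  Identical seeds give bitwise identical
#' traces (internal RNG, independent of R's RNG state).
#'
#' @param model `"n4"` or `"p2"`
#' @param V_command commanded potential (mV) on the `dt_ms` grid
#' @param dt_ms sampling/rate-refresh step (ms); per-channel exit rate times
#'   `dt_ms` must stay below 0.1
#' @param population a [channel_population()]
#' @param seed integer seed (required)
#' @param A,B p2 rate factors
#' @param burn_ms discarded burn-in (ms)
#' @return A data frame of class `markov_trace`: `time_ms`, state counts
#'   `N0..`, `open` (open-channel count).  Attributes: `model`, `dt_ms`,
#'   `population`, `seed`.
#' @export
simulate_markov <- function(model = c("n4", "p2"), V_command, dt_ms = 0.01,
                            population = channel_population(), seed,
                            A = 0.35, B = 4, burn_ms = 50) {
  model <- match.arg(model)
  stopifnot(is.numeric(V_command), length(V_command) >= 1, dt_ms > 0)
  if (missing(seed)) stop("an integer seed is required for reproducibility")

  # per-channel exit-rate guard over the commanded range
  vr <- range(V_command)
  vv <- seq(vr[1], vr[2], length.out = 32)
  rmax <- if (model == "n4") {
    rn <- hh_gate_rates(vv, "n")
    max(4 * rn$alpha, 4 * rn$beta, 3 * rn$alpha + rn$beta,
        rn$alpha + 3 * rn$beta, 2 * (rn$alpha + rn$beta))
  } else {
    r <- p2_rates(vv, A, B)
    max(r$k1, r$k2 + r$k3, r$k4)
  }
  if (rmax * dt_ms >= 0.1)
    stop("dt_ms too large: max exit rate * dt = ", signif(rmax * dt_ms, 3),
         " >= 0.1; reduce dt_ms")

  nb <- round(burn_ms / dt_ms)
  V <- c(rep(V_command[1], nb), V_command)
  p0 <- stationary_distribution(model, V_command[1], A, B)
  code <- if (model == "p2") 2L else 0L
  counts <- gillespie_cpp(code, V, dt_ms, population$N_K, A, B, p0,
                          as.double(seed %% 2^31), as.double(seed %/% 2^31))
  counts <- counts[(nb + 1):nrow(counts), , drop = FALSE]
  S <- ncol(counts)
  df <- as.data.frame(counts)
  names(df) <- paste0("N", 0:(S - 1))
  df <- cbind(time_ms = (seq_len(nrow(df)) - 1) * dt_ms, df,
              open = counts[, S])
  structure(df, model = model, dt_ms = dt_ms, population = population,
            seed = seed, A = A, B = B,
            class = c("markov_trace", "data.frame"))
}

#' Fluctuating potassium current of a Markov trace
#'
#' `I_K(t) = open(t) * gamma_K * (V(t) - V_K)` in pA.
#'
#' @param trace a [simulate_markov()] trace
#' @param V_command commanded potential on the same grid (mV); defaults to
#'   the recycled scalar clamp level if of length 1
#' @param population the [channel_population()] used for the simulation
#' @return Numeric current vector (pA).
#' @export
fluctuating_current <- function(trace, V_command,
                                population = attr(trace, "population")) {
  if (length(V_command) == 1) V_command <- rep(V_command, nrow(trace))
  if (length(V_command) != nrow(trace))
    stop("V_command and trace are not on the same grid")
  trace$open * population$gamma_pS * (V_command - population$V_K) * 1e-3
}

one_sided_periodogram <- function(y, dt_s) {
  n <- length(y)
  2 * dt_s / n * Mod(fft(y - mean(y)))^2
}

#' Empirical one-sided power spectral density
#'
#' Mean-subtracted rectangular-window periodogram per trace, averaged
#' arithmetically across traces (each trace is one segment).  The one-sided
#' density scaling satisfies Parseval: `sum(psd) * df` equals the average
#' sample variance, so the estimator converges to the analytic fluctuation
#' spectra under matched conventions.
#'
#' @param current_traces list of equal-length numeric vectors (pA)
#' @param dt_ms sampling step (ms)
#' @return Data frame `f_Hz`, `psd` (pA^2/Hz), with attribute
#'   `n_iterations`.
#' @export
empirical_psd <- function(current_traces, dt_ms) {
  if (!is.list(current_traces)) current_traces <- list(current_traces)
  len <- unique(vapply(current_traces, length, integer(1)))
  if (length(len) != 1) stop("traces must have equal length")
  dt_s <- dt_ms * 1e-3
  acc <- 0
  for (y in current_traces) acc <- acc + one_sided_periodogram(y, dt_s)
  acc <- acc / length(current_traces)
  n <- len
  j <- seq_len(floor((n - 1) / 2))
  structure(data.frame(f_Hz = j / (n * dt_s), psd = acc[j + 1]),
            n_iterations = length(current_traces))
}

#' Averaged Markov fluctuation spectrum of a channel population
#'
#' Convenience driver: simulates `iterations` independent Markov records at
#' a clamp level (with an optional multi-sine stimulus superimposed),
#' computes the fluctuating current of each, and accumulates the averaged
#' one-sided periodogram without retaining the traces.
#'
#' @inheritParams simulate_markov
#' @param V0 clamp level (mV)
#' @param duration_ms record length per iteration (ms); with the default
#'   1000 ms the frequency resolution is 1 Hz
#' @param iterations number of Monte-Carlo records
#' @param stimulus optional [stimulus_spec()] added to `V0`
#' @param seed base seed; iteration `i` uses `seed + i - 1`
#' @return As [empirical_psd()], with attribute `mean_current_pA`.
#' @export
markov_psd <- function(model = c("n4", "p2"), V0, population = channel_population(),
                       duration_ms = 1000, dt_ms = 0.01, iterations = 128,
                       seed = 1, stimulus = NULL, A = 0.35, B = 4,
                       burn_ms = 50) {
  model <- match.arg(model)
  n <- round(duration_ms / dt_ms)
  V <- rep(V0, n)
  if (!is.null(stimulus))
    V <- V + synthesize_multisine(stimulus, dt_ms, duration_ms)
  dt_s <- dt_ms * 1e-3
  acc <- 0; imean <- 0
  for (it in seq_len(iterations)) {
    tr <- simulate_markov(model, V, dt_ms, population, seed = seed + it - 1,
                          A = A, B = B, burn_ms = burn_ms)
    cur <- fluctuating_current(tr, V, population)
    acc <- acc + one_sided_periodogram(cur, dt_s)
    imean <- imean + mean(cur)
  }
  acc <- acc / iterations
  j <- seq_len(floor((n - 1) / 2))
  structure(data.frame(f_Hz = j / (n * dt_s), psd = acc[j + 1]),
            n_iterations = iterations, mean_current_pA = imean / iterations)
}
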