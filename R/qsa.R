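# Fourier coefficients of a real record: coef[n + 1] = (1/N) sum y exp(-i w_n t),
# exact for frequencies on the bin grid n/T.
fourier_coefficients <- function(y) fft(y) / length(y)

# signed index bookkeeping over Gamma = (-N..-1, 1..N)
gamma_index <- function(N) c(-(N:1), 1:N)

#' Estimate the QSA decomposition of a response
#'
#' Fourier-analyzes one full stimulus period of the response and identifies
#' the quadratic sinusoidal analysis decomposition
#' `y(t) = y0 + sum_k l_k x_k e^{i w_k t} + sum_{i,j} b_{i,j} x_i x_j
#' e^{i(w_i + w_j)t}`: the DC term `y0`, the linear coefficients `l_k` at
#' the stimulus frequencies, and the Hermitian QSA matrix `Q` with
#' `Q[i, j] = b_{-i, j}` over the signed index set Gamma.
#'
#' Because the stimulus is overlap-free, every second-order output bin has a
#' unique unordered source pair; only the symmetric sum `b_{i,j} + b_{j,i}`
#' is identifiable from one bin, so the estimator uses the symmetric
#' convention `b_{i,j} = b_{j,i}` and splits each measured bin equally.  By
#' the DC convention `b_{-k,k} = 0` (the diagonal of `Q` is zero) and all DC
#' goes to `y0`; a `baseline` (the steady-state response at the clamp level)
#' is subtracted first so `y0` captures only the stimulus-induced DC shift.
#'
#' The analysis window is the last part of `response` after `skip_ms` and
#' must contain exactly one full period; the stimulus window is re-created
#' internally over the same absolute times, so any circular shift of the
#' record leaves the coefficients invariant.
#'
#' @param spec a [stimulus_spec()]; must be overlap-free
#' @param response response samples on the `dt_ms` grid, starting at time 0,
#'   of length `(skip_ms + T)/dt_ms`
#' @param dt_ms sampling step (ms)
#' @param skip_ms transient to discard (ms); must be a grid multiple
#' @param baseline steady-state response level to subtract (same units as
#'   `response`)
#' @return An object of class `qsa_result`: list with `y0`, `L` (complex,
#'   over Gamma), `Q` (complex 2N x 2N, Hermitian), `gamma`, `multipliers`,
#'   `f_Hz` (signed), `x` (signed stimulus coefficients), `spec`, `dt_ms`.
#' @export
estimate_qsa <- function(spec, response, dt_ms, skip_ms = 0, baseline = 0) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (nrow(check_overlap(spec$multipliers)) > 0)
    stop("stimulus multipliers overlap at first/second order")
  T_ms <- spec$period_s * 1000
  nper <- round(T_ms / dt_ms)
  nskip <- round(skip_ms / dt_ms)
  if (abs(skip_ms / dt_ms - nskip) > 1e-9) stop("skip_ms must lie on the grid")
  if (length(response) < nskip + nper)
    stop("response must cover skip_ms plus one full period")
  if (length(response) > nskip + nper)
    response <- response[seq_len(nskip + nper)]

  y <- response[(nskip + 1):(nskip + nper)] - baseline
  x <- synthesize_multisine(spec, dt_ms, T_ms, t0_ms = nskip * dt_ms)
  yc <- fourier_coefficients(y)
  xc <- fourier_coefficients(x)

  m <- spec$multipliers
  N <- length(m)
  xk <- xc[m + 1]                     # measured stimulus coefficients, k > 0
  lk <- yc[m + 1] / xk

  g <- gamma_index(N)
  nsig <- c(-rev(m), m)               # signed multipliers over Gamma
  xsig <- c(Conj(rev(xk)), xk)

  # output bin of Q[a, b] is n_b - n_a (the pair (-a, b)); ybin() looks the
  # measured coefficient up with conjugation for negative frequencies
  ybin <- function(n) {
    v <- complex(length.out = length(n))
    pos <- n > 0; neg <- n < 0
    v[pos] <- yc[n[pos] + 1]
    v[neg] <- Conj(yc[-n[neg] + 1])
    v
  }
  ns <- outer(nsig, nsig, function(a, b) b - a)
  cfac <- matrix(2, 2 * N, 2 * N)
  cfac[outer(nsig, nsig, "+") == 0] <- 1   # doubling bins: single source term
  Q <- matrix(ybin(ns), 2 * N, 2 * N) /
    (cfac * outer(Conj(xsig), xsig))
  diag(Q) <- 0 + 0i                        # b_{-k,k} = 0 by convention

  structure(list(y0 = Re(yc[1]), L = c(Conj(rev(lk)), lk), Q = Q,
                 gamma = g, multipliers = m, n_signed = nsig,
                 f_Hz = nsig / spec$period_s, x = xsig,
                 spec = spec, dt_ms = dt_ms),
            class = "qsa_result")
}

#' @export
print.qsa_result <- function(x, ...) {
  N <- length(x$multipliers)
  cat(sprintf("QSA result: %d stimulus frequencies, y0 = %.4g\n", N, x$y0))
  cat(sprintf("  max |l_k| = %.4g, max |Q| = %.4g\n",
              max(abs(x$L)), max(abs(x$Q))))
  invisible(x)
}

#' Reconstruct the response waveform from a QSA decomposition
#'
#' Builds `y0 + y1(t) + y2(t)` on the sampling grid from the estimated
#' coefficients; useful to quantify how much of a response the quadratic
#' model explains (the residual bounds third-order leakage).
#'
#' @param result a [estimate_qsa()] result
#' @return Numeric vector over one period, in the time reference of the
#'   analysis window (t = 0 at the start of the analyzed period).
#' @export
qsa_reconstruct <- function(result) {
  spec <- result$spec
  T_ms <- spec$period_s * 1000
  n <- round(T_ms / result$dt_ms)
  t <- (seq_len(n) - 1) * result$dt_ms
  w <- 2 * pi * result$n_signed / (T_ms)   # rad/ms, signed
  y <- rep(result$y0 + 0i, n)
  for (a in seq_along(result$gamma))
    y <- y + result$L[a] * result$x[a] * exp(1i * w[a] * t)
  for (a in seq_along(result$gamma)) for (b in seq_along(result$gamma)) {
    q <- result$Q[a, b]
    if (q == 0) next
    # Q[a,b] = b_{-a,b}: contribution b_{-a,b} x_{-a} x_b at w_b - w_a
    y <- y + q * Conj(result$x[a]) * result$x[b] * exp(1i * (w[b] - w[a]) * t)
  }
  Re(y)
}

spectrum_table <- function(kind, multiplier, period_s, power,
                           count = rep(1L, length(power))) {
  ord <- order(multiplier)
  structure(data.frame(kind = kind, multiplier = multiplier[ord],
                       f_Hz = multiplier[ord] / period_s,
                       power = power[ord], count = count[ord]),
            period_s = period_s,
            class = c("spectrum_table", "data.frame"))
}

#' Column power spectrum of a QSA matrix
#'
#' The mean squared quadratic output by matrix columns,
#' `S_R(w_j) = (1/2N) sum_{i in Gamma} |Q[i,j] conj(x_i) x_j|^2`, indexed at
#' the fundamental frequencies.
#'
#' @param result a [estimate_qsa()] result
#' @return A `spectrum_table` data frame (`kind = "S_R"`).
#' @export
qsa_column_power <- function(result) {
  N <- length(result$multipliers)
  pos <- (N + 1):(2 * N)     # columns at positive frequencies
  power <- vapply(pos, function(j) {
    sum(abs(result$Q[, j] * Conj(result$x) * result$x[j])^2) / (2 * N)
  }, numeric(1))
  spectrum_table("S_R", result$multipliers, result$spec$period_s, power)
}

#' Single-trial multi-sinusoidal power spectra
#'
#' Partitions the Fourier coefficients of one response period by frequency
#' support and returns the power spectra of the paper's averaging algorithm:
#' `S_L` at fundamental frequencies, `S_D` at frequency doubling, `S_P` at
#' frequency sums and `S_M` at frequency differences (distinct pairs), all
#' measured directly from the output bins.  Optionally also `S_R` via
#' [qsa_column_power()].
#'
#' @inheritParams estimate_qsa
#' @param include_column_power also compute `S_R` (runs the full QSA
#'   estimator)
#' @return A named list of `spectrum_table` data frames
#'   (`S_L`, `S_D`, `S_P`, `S_M`, and optionally `S_R`).
#' @export
single_trial_spectra <- function(spec, response, dt_ms, skip_ms = 0,
                                 baseline = 0, include_column_power = FALSE) {
  stopifnot(inherits(spec, "stimulus_spec"))
  T_ms <- spec$period_s * 1000
  nper <- round(T_ms / dt_ms)
  nskip <- round(skip_ms / dt_ms)
  if (length(response) < nskip + nper)
    stop("response must cover skip_ms plus one full period")
  y <- response[(nskip + 1):(nskip + nper)] - baseline
  yc <- fourier_coefficients(y)
  m <- spec$multipliers
  n <- length(m)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  p2 <- function(mult) abs(yc[mult + 1])^2
  out <- list(
    S_L = spectrum_table("S_L", m, spec$period_s, p2(m)),
    S_D = spectrum_table("S_D", 2L * m, spec$period_s, p2(2L * m)),
    S_P = spectrum_table("S_P", m[i] + m[j], spec$period_s, p2(m[i] + m[j])),
    S_M = spectrum_table("S_M", m[j] - m[i], spec$period_s, p2(m[j] - m[i])))
  if (include_column_power)
    out$S_R <- qsa_column_power(
      estimate_qsa(spec, response, dt_ms, skip_ms, baseline))
  out
}

#' Average power spectra over trials with redundancy counting
#'
#' Merges the frequency sets of several single-trial spectra (each from its
#' own overlap-free stimulus) and averages the power at each frequency,
#' dividing by the number of trials in which the frequency occurs (the
#' redundancy counts over the merged first- and second-order sets).
#'
#' @param trials a list; each element a named list of `spectrum_table`s as
#'   returned by [single_trial_spectra()]
#' @return A named list of merged `spectrum_table`s, one per spectrum kind
#'   present in all trials; the `count` column holds the redundancy counts.
#' @export
accumulate_spectra <- function(trials) {
  if (!length(trials)) stop("empty trial list")
  kinds <- Reduce(intersect, lapply(trials, names))
  period <- attr(trials[[1]][[kinds[1]]], "period_s")
  out <- lapply(kinds, function(kind) {
    tabs <- lapply(trials, `[[`, kind)
    if (any(vapply(tabs, function(tb) !isTRUE(all.equal(attr(tb, "period_s"),
                                                        period)), logical(1))))
      stop("all trials must share the same base period")
    all <- do.call(rbind, lapply(tabs, as.data.frame))
    ag <- aggregate(cbind(power = all$power) ~ multiplier, data = all, FUN = sum)
    cnt <- aggregate(cbind(count = all$power) ~ multiplier, data = all,
                     FUN = length)
    spectrum_table(kind, ag$multiplier, period, ag$power / cnt$count,
                   as.integer(cnt$count))
  })
  names(out) <- kinds
  out
}

#' Averaged QSA power of stochastic responses to one stimulus
#'
#' Runs the QSA estimator on each of several responses to the *same*
#' stimulus (e.g. independent Markov simulations) and averages `|Q|^2`
#' elementwise — the average QSA Markov noise power spectrum.  Optionally
#' removes the harmonic diagonal: entries whose output frequency is a
#' doubled stimulus frequency `2 |w_k|` are set to zero.
#'
#' @inheritParams estimate_qsa
#' @param responses list of response vectors (>= 2), all to the same
#'   stimulus and of equal length
#' @param remove_diagonal zero the harmonic (frequency-doubling) entries
#' @return Numeric matrix of averaged `|Q|^2` over Gamma x Gamma, with the
#'   signed multipliers as attribute `n_signed` and the per-entry output
#'   multiplier as attribute `n_out`.
#' @export
qsa_markov_noise_power <- function(spec, responses, dt_ms, skip_ms = 0,
                                   baseline = 0, remove_diagonal = FALSE) {
  if (!is.list(responses) || length(responses) < 2)
    stop("need at least 2 response iterations")
  len <- unique(vapply(responses, length, integer(1)))
  if (length(len) != 1)
    stop("responses have unequal lengths: not the same stimulus record")
  acc <- NULL
  for (r in responses) {
    q <- estimate_qsa(spec, r, dt_ms, skip_ms, baseline)
    a2 <- abs(q$Q)^2
    acc <- if (is.null(acc)) a2 else acc + a2
  }
  avg <- acc / length(responses)
  nsig <- c(-rev(spec$multipliers), spec$multipliers)
  n_out <- outer(nsig, nsig, function(a, b) b - a)
  if (remove_diagonal) avg[outer(nsig, nsig, "+") == 0] <- 0
  structure(avg, n_signed = nsig, n_out = n_out,
            iterations = length(responses))
}

#' Relative deviation between two QSA power matrices
#'
#' Frobenius-norm relative deviation `||A - B|| / ||B||`, used to quantify
#' how far an averaged stochastic `|Q|^2` lies from its deterministic
#' reference.
#'
#' @param A,B numeric matrices of equal dimension
#' @return Scalar deviation.
#' @export
qsa_matrix_deviation <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  sqrt(sum((A - B)^2)) / sqrt(sum(B^2))
}
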