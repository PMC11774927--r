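# enumerate second-order combination frequencies of an integer multiplier set
second_order_combinations <- function(multipliers) {
  m <- as.integer(multipliers)
  n <- length(m)
  pairs_i <- pairs_j <- integer(0)
  if (n >= 2) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs_i <- idx[, 1]; pairs_j <- idx[, 2]
  }
  data.frame(
    value = c(2L * m, m[pairs_i] + m[pairs_j], m[pairs_j] - m[pairs_i]),
    kind = rep(c("double", "sum", "difference"),
               c(n, length(pairs_i), length(pairs_i))),
    source = c(sprintf("%d+%d", m, m),
               sprintf("%d+%d", m[pairs_i], m[pairs_j]),
               sprintf("%d-%d", m[pairs_j], m[pairs_i])))
}

#' Check a multiplier set for first/second order frequency overlap
#'
#' Enumerates all second-order combination frequencies of an integer
#' multiplier set (sums `n_i + n_j` for i <= j, differences `|n_i - n_j|`,
#' doublings `2 n_k`) and reports every coincidence with a first-order
#' multiplier and every coincidence between two distinct unordered source
#' pairs.  An empty result means the set can be used for quadratic
#' sinusoidal analysis: every second-order output bin then has a unique
#' source pair.
#'
#' @param multipliers distinct positive integers (frequency multipliers of
#'   the base frequency 1/T); at least 2
#' @return A data frame of violations with columns `value`, `kind`
#'   (`"first_order"` or `"second_order"`), `detail`; zero rows if the set
#'   is overlap-free.
#' @examples
#' nrow(check_overlap(c(1, 2, 3, 4)))   # > 0: e.g. 1 + 2 = 3
#' nrow(check_overlap(c(2, 3, 10, 21))) # 0
#' @export
check_overlap <- function(multipliers) {
  m <- as.integer(multipliers)
  if (length(m) < 2) stop("need at least 2 multipliers")
  if (any(m <= 0) || anyDuplicated(m))
    stop("multipliers must be distinct positive integers")
  co <- second_order_combinations(m)
  viol <- list()
  hit1 <- co$value %in% m
  if (any(hit1))
    viol$first <- data.frame(value = co$value[hit1], kind = "first_order",
      detail = sprintf("%s (%s) coincides with multiplier %d",
                       co$source[hit1], co$kind[hit1], co$value[hit1]))
  dup <- co$value[duplicated(co$value)]
  if (length(dup)) {
    dup <- unique(dup)
    viol$second <- do.call(rbind, lapply(dup, function(v) {
      src <- co$source[co$value == v]
      data.frame(value = v, kind = "second_order",
                 detail = paste0("combinations {", paste(src, collapse = ", "),
                                 "} coincide at ", v))
    }))
  }
  if (length(viol)) do.call(rbind, unname(viol))
  else data.frame(value = integer(0), kind = character(0),
                  detail = character(0))
}

#' Generate a random non-overlapping multiplier set
#'
#' Builds a set of integer frequency multipliers free of first/second order
#' overlap by incremental rejection: multipliers are added one at a time,
#' candidates that would create any overlap are rejected, and the
#' construction restarts when a slot exhausts its candidate budget.  (For
#' sets of realistic size, e.g. 21 multipliers below 1000, a uniformly drawn
#' whole set is essentially never overlap-free, so set-wise rejection would
#' not terminate.)  Deterministic given `seed`.
#'
#' @param n_freq number of multipliers
#' @param multiplier_range integer range `c(lo, hi)` to draw from
#' @param seed optional integer seed (R RNG, restored on exit)
#' @param tries_per_slot candidate budget per slot before restarting
#' @param max_restarts restart budget before giving up
#' @return Sorted integer vector of length `n_freq` passing
#'   [check_overlap()].
#' @export
generate_nonoverlapping_set <- function(n_freq, multiplier_range = c(1, 1000),
                                        seed = NULL, tries_per_slot = 2000L,
                                        max_restarts = 50L) {
  stopifnot(n_freq >= 2, length(multiplier_range) == 2)
  lo <- as.integer(multiplier_range[1]); hi <- as.integer(multiplier_range[2])
  if (hi - lo + 1 < n_freq) stop("multiplier_range too small")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  for (restart in seq_len(max_restarts)) {
    sel <- integer(0)
    vals <- integer(0)  # occupied second-order values
    repeat {
      ok <- FALSE
      for (try in seq_len(tries_per_slot)) {
        cand <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        if (cand %in% sel) next
        new_vals <- c(2L * cand, cand + sel, abs(cand - sel))
        first <- c(sel, cand)
        if (any(new_vals %in% first) || any(first %in% vals) ||
            any(new_vals %in% vals) || anyDuplicated(new_vals)) next
        sel <- c(sel, cand); vals <- c(vals, new_vals); ok <- TRUE
        break
      }
      if (!ok) break
      if (length(sel) == n_freq) return(sort(sel))
    }
  }
  stop("could not build a non-overlapping set; enlarge multiplier_range")
}

#' The canonical 21-frequency stimulus multipliers
#'
#' The integer multipliers (base period 1 s) used throughout for
#' deterministic fixtures; the set is overlap-free at first and second
#' order.
#' @return Integer vector of length 21.
#' @export
canonical_multipliers <- function() {
  c(2L, 3L, 10L, 21L, 35L, 50L, 76L, 104L, 134L, 143L, 223L, 239L, 285L,
    388L, 405L, 515L, 564L, 636L, 815L, 892L, 982L)
}

#' Multi-sinusoidal stimulus specification
#'
#' A real multi-sine `x(t) = sum_k 2 |x_k| cos(w_k t + theta_k)` over the
#' index set Gamma = (-N..-1, 1..N) with conjugate-symmetric complex
#' coefficients `x_k = (amplitude/2) e^{i theta_k}`, so each component has
#' peak amplitude `amplitude_mV`.  Frequencies are integer multiples of
#' `1/period_s`.  Phases default to pseudo-random values in `[0, pi]`
#' (`phase_range = 2*pi` gives the conventional full circle).
#'
#' @param multipliers distinct positive integers, strictly increasing after
#'   sorting
#' @param period_s base period T (s); lowest resolvable frequency 1/T
#' @param amplitude_mV per-component peak amplitude (mV)
#' @param phases explicit phases (rad), or `NULL` to draw them
#' @param seed seed for phase randomization (R RNG, restored on exit)
#' @param phase_range upper end of the uniform phase distribution (rad)
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(multipliers, period_s = 1, amplitude_mV = 0.25,
                          phases = NULL, seed = NULL, phase_range = pi) {
  m <- sort(as.integer(multipliers))
  if (any(m <= 0) || anyDuplicated(m))
    stop("multipliers must be distinct positive integers")
  N <- length(m)
  if (is.null(phases)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    phases <- runif(N, 0, phase_range)
  }
  stopifnot(length(phases) == N)
  structure(list(multipliers = m, period_s = period_s,
                 amplitude_mV = amplitude_mV, phases = phases,
                 f_Hz = m / period_s,
                 x_k = amplitude_mV / 2 * exp(1i * phases)),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Multi-sine stimulus: %d components, T = %g s, amplitude %g mV\n",
              length(x$multipliers), x$period_s, x$amplitude_mV))
  cat("  f (Hz):", paste(signif(x$f_Hz, 4), collapse = " "), "\n")
  invisible(x)
}

#' Synthesize a multi-sinusoidal waveform
#'
#' Samples the stimulus on a uniform grid.  The step must divide the base
#' period, so that any analysis window of exactly one period puts every
#' stimulus (and second-order) frequency on an exact Fourier bin; records
#' may be longer than one period to accommodate a transient.
#'
#' @param spec a [stimulus_spec()]
#' @param dt_ms sampling step (ms)
#' @param duration_ms record duration (ms); defaults to one period
#' @param t0_ms time origin (ms), useful for phase-consistent windows
#' @param derivative also return the analytic time derivative (mV/ms) as
#'   attribute `dxdt`
#' @return Numeric waveform (mV), zero-mean over each full period.
#' @export
synthesize_multisine <- function(spec, dt_ms, duration_ms = spec$period_s * 1000,
                                 t0_ms = 0, derivative = FALSE) {
  T_ms <- spec$period_s * 1000
  if (abs(T_ms / dt_ms - round(T_ms / dt_ms)) > 1e-9)
    stop("dt_ms must divide the stimulus period")
  if (abs(duration_ms / dt_ms - round(duration_ms / dt_ms)) > 1e-9)
    stop("duration_ms must lie on the dt grid")
  f_max2 <- 2 * max(spec$f_Hz)            # highest second-order frequency
  if (f_max2 >= 1 / (2 * dt_ms * 1e-3))
    stop("Nyquist violation: 2*max(f) = ", f_max2,
         " Hz >= 1/(2 dt); reduce dt_ms")
  n <- round(duration_ms / dt_ms)
  t <- t0_ms + (seq_len(n) - 1) * dt_ms
  x <- numeric(n)
  dx <- if (derivative) numeric(n)
  for (k in seq_along(spec$multipliers)) {
    w <- 2 * pi * spec$f_Hz[k] / 1000     # rad/ms
    ph <- w * t + spec$phases[k]
    x <- x + spec$amplitude_mV * cos(ph)
    if (derivative) dx <- dx - spec$amplitude_mV * w * sin(ph)
  }
  if (derivative) attr(x, "dxdt") <- dx
  x
}

#' Read or write a stimulus specification as JSON
#'
#' The on-disk form records the base period, integer multipliers, component
#' amplitude and explicit phases, so a stimulus can be reproduced exactly.
#'
#' @param spec a [stimulus_spec()]
#' @param path JSON file path
#' @return `write_stimulus_spec()` returns `path` invisibly;
#'   `read_stimulus_spec()` returns a `stimulus_spec`.
#' @export
write_stimulus_spec <- function(spec, path) {
  jsonlite::write_json(list(period_s = spec$period_s,
                            multipliers = spec$multipliers,
                            amplitude_mV = spec$amplitude_mV,
                            phases = spec$phases),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_spec
#' @export
read_stimulus_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_spec(j$multipliers, period_s = j$period_s,
                amplitude_mV = j$amplitude_mV, phases = j$phases)
}
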