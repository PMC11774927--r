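test_that("a linear system yields a zero Q matrix and the filter's L", {
  h <- function(f) 1 / (1 + 1i * f / 50)
  spec <- stimulus_spec(canonical_multipliers(), amplitude_mV = 0.25, seed = 7)
  dt <- 0.05
  x <- synthesize_multisine(spec, dt)
  n <- length(x)
  fbin <- c(0:(n / 2), -((n / 2 - 1):1))
  y <- Re(fft(fft(x) / n * h(fbin), inverse = TRUE))
  q <- estimate_qsa(spec, y, dt)
  N <- length(spec$multipliers)
  expect_lt(max(abs(q$Q)), 1e-12)
  expect_equal(q$L[(N + 1):(2 * N)], h(spec$f_Hz), tolerance = 1e-12)
  expect_lt(abs(q$y0), 1e-12)
})

test_that("the squarer fixture is recovered exactly", {
  spec <- stimulus_spec(c(3L, 10L), period_s = 1, amplitude_mV = 1,
                        phases = c(0.4, 1.1))
  dt <- 0.05
  x <- synthesize_multisine(spec, dt)
  q <- estimate_qsa(spec, x^2, dt)
  # (sum_k x_k e^{iw_k t})^2 has b_{i,j} = 1 for every pair; DC -> y0
  Qexp <- matrix(1 + 0i, 4, 4)
  diag(Qexp) <- 0
  expect_equal(q$Q, Qexp, tolerance = 1e-12)
  expect_equal(q$y0, 2 * sum(abs(spec$x_k)^2), tolerance = 1e-12)
  expect_lt(max(abs(q$L)), 1e-12)
  # column power against the hand-computed sum
  sr <- qsa_column_power(q)
  xsig <- c(Conj(rev(spec$x_k)), spec$x_k)
  hand <- sapply(3:4, function(j)
    sum(abs(Qexp[, j] * Conj(xsig) * xsig[j])^2) / 4)
  expect_equal(sr$power, hand, tolerance = 1e-12)
  # single-trial spectra of the squarer: S_P at f1+f2 equals |2 x1 x2|^2
  st <- single_trial_spectra(spec, x^2, dt)
  expect_equal(st$S_P$power, abs(2 * spec$x_k[1] * spec$x_k[2])^2,
               tolerance = 1e-12)
  expect_equal(st$S_D$power, abs(spec$x_k)^4, tolerance = 1e-12)
  expect_equal(st$S_M$power, abs(2 * Conj(spec$x_k[1]) * spec$x_k[2])^2,
               tolerance = 1e-12)
  expect_lt(max(st$S_L$power), 1e-20)
})

test_that("the ODE response decomposition is Hermitian and nearly complete", {
  spec <- stimulus_spec(canonical_multipliers(), amplitude_mV = 0.25, seed = 3)
  run <- ode_qsa_response("n4", 5, spec)
  q <- estimate_qsa(spec, run$response, 0.01, skip_ms = 100,
                    baseline = run$baseline)
  expect_lt(max(abs(q$Q - Conj(t(q$Q)))), 1e-10)
  expect_equal(eigen(q$Q, only.values = TRUE)$values,
               Re(eigen(q$Q, only.values = TRUE)$values), tolerance = 1e-10)
  # reconstruction captures the response up to third-order leakage
  yrec <- qsa_reconstruct(q)
  yact <- run$response[(100 / 0.01 + 1):length(run$response)] - run$baseline
  expect_lt(sqrt(mean((yrec - yact)^2)) / sqrt(mean(yact^2)), 1e-3)
  # S_L equals |l_k x_k|^2 by construction
  st <- single_trial_spectra(spec, run$response, 0.01, skip_ms = 100,
                             baseline = run$baseline)
  N <- length(spec$multipliers)
  expect_equal(st$S_L$power,
               abs(q$L[(N + 1):(2 * N)] * q$x[(N + 1):(2 * N)])^2,
               tolerance = 1e-12)
})

test_that("estimator input contracts are enforced", {
  bad <- stimulus_spec(c(1L, 2L, 3L, 4L))
  expect_error(estimate_qsa(bad, rep(0, 20000), 0.05), "overlap")
  spec <- stimulus_spec(c(3L, 10L))
  expect_error(estimate_qsa(spec, rep(0, 100), 0.05), "full period")
})

test_that("spectrum accumulation counts redundancies correctly", {
  tab <- function(kind, mult, pow)
    channelspectra:::spectrum_table(kind, mult, 1, pow)
  t1 <- list(S_L = tab("S_L", c(2L, 5L), c(1, 4)))
  t2 <- list(S_L = tab("S_L", c(5L, 9L), c(2, 8)))
  avg <- accumulate_spectra(list(t1, t2))
  expect_equal(avg$S_L$multiplier, c(2L, 5L, 9L))
  expect_equal(avg$S_L$power, c(1, 3, 8))     # 5 Hz averaged over 2 trials
  expect_equal(avg$S_L$count, c(1L, 2L, 1L))
  # idempotence over identical trials
  same <- accumulate_spectra(list(t1, t1, t1))
  expect_equal(same$S_L$power, t1$S_L$power)
  expect_equal(same$S_L$count, c(3L, 3L))
  expect_error(accumulate_spectra(list()), "empty")
})

test_that("averaged quadratic spectra fall on the diagonal but flatten by columns", {
  trials <- lapply(1:12, function(m) {
    mult <- generate_nonoverlapping_set(21, c(1, 1000), seed = 1000 + m)
    sp <- stimulus_spec(mult, amplitude_mV = 0.25, seed = 2000 + m)
    run <- ode_qsa_response("n4", 5, sp)
    single_trial_spectra(sp, run$response, 0.01, skip_ms = 100,
                         baseline = run$baseline,
                         include_column_power = TRUE)
  })
  avg <- accumulate_spectra(trials)
  ratio <- function(tb) {
    q <- quantile(tb$f_Hz, c(0.2, 0.8))
    median(tb$power[tb$f_Hz >= q[2]]) / median(tb$power[tb$f_Hz <= q[1]])
  }
  expect_lt(ratio(avg$S_D), ratio(avg$S_R))   # S_D keeps falling, S_R flattens
  expect_gt(min(avg$S_R$power), 0)
})

test_that("averaged Markov QSA power behaves and removes the harmonic diagonal", {
  spec <- stimulus_spec(c(3L, 10L), period_s = 0.2, amplitude_mV = 1,
                        phases = c(0.3, 2.1))
  dt <- 0.05
  x <- synthesize_multisine(spec, dt, 300)
  run <- lapply(1:2, function(i) {
    tr <- integrate_voltage_clamp("p2", 55 + x, dt)
    tr$I_total
  })
  # deterministic responses repeated: average equals the single-trial |Q|^2
  avg <- qsa_markov_noise_power(spec, run, dt, skip_ms = 100)
  q1 <- estimate_qsa(spec, run[[1]], dt, skip_ms = 100)
  expect_equal(as.vector(avg), as.vector(abs(q1$Q)^2), tolerance = 1e-12)
  # harmonic entries (output frequency 2|w_k|) are zeroed on request
  avg0 <- qsa_markov_noise_power(spec, run, dt, skip_ms = 100,
                                 remove_diagonal = TRUE)
  nsig <- attr(avg0, "n_signed")
  harm <- outer(nsig, nsig, "+") == 0
  expect_true(all(avg0[harm] == 0))
  expect_equal(avg0[!harm], avg[!harm])
  expect_error(qsa_markov_noise_power(spec, run[1], dt), "at least 2")
  expect_error(qsa_markov_noise_power(spec, list(run[[1]], run[[2]][-1]), dt),
               "unequal")
})
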