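test_that("traces are seed-deterministic and conserve the channel count", {
  pop <- channel_population(18, 50)           # 900 channels: fast
  t1 <- simulate_markov("n4", rep(5, 20001), 0.01, pop, seed = 3)
  t2 <- simulate_markov("n4", rep(5, 20001), 0.01, pop, seed = 3)
  expect_identical(t1, t2)
  t3 <- simulate_markov("n4", rep(5, 20001), 0.01, pop, seed = 4)
  expect_false(identical(t1$open, t3$open))
  expect_true(all(rowSums(t1[paste0("N", 0:4)]) == pop$N_K))
  tp <- simulate_markov("p2", rep(55, 20001), 0.01, pop, seed = 5)
  expect_true(all(rowSums(tp[paste0("N", 0:2)]) == pop$N_K))
  expect_true(all(tp$open >= 0 & tp$open <= pop$N_K))
})

test_that("stationary open fractions match the master-equation steady states", {
  pop <- channel_population()                  # 9000 channels
  for (case in list(list("n4", 5), list("n4", 55),
                    list("p2", 5), list("p2", 55))) {
    model <- case[[1]]; v <- case[[2]]
    p <- if (model == "n4") hh_gate_rates(v, "n")$x_inf^4
         else p2_steady_state(v)$p2_inf
    tr <- simulate_markov(model, rep(v, 100001), 0.01, pop,
                          seed = 7 + v + (model == "p2"))
    # effective sample count: channels x record length / (10 tau)
    tau <- hh_gate_rates(v, "n")$tau
    neff <- pop$N_K * 1000 / (10 * tau)
    se <- sqrt(p * (1 - p) / neff)
    expect_lt(abs(mean(tr$open) / pop$N_K - p), 3 * se)
  }
})

test_that("the stationary state occupancy is binomial in n_inf", {
  pop <- channel_population()
  tr <- simulate_markov("n4", rep(55, 50001), 0.01, pop, seed = 21)
  obs <- as.numeric(tr[25001, paste0("N", 0:4)])   # one stationary snapshot
  expected <- stationary_distribution("n4", 55)
  pval <- suppressWarnings(chisq.test(obs, p = expected)$p.value)
  expect_gt(pval, 0.01)
})

test_that("the chain absorbs into the closed state when opening rates vanish", {
  # at a deep hyperpolarization alpha_n is ~ 1e-9/ms: effectively absorbing
  pop <- channel_population()
  tr <- simulate_markov("n4", rep(-200, 10001), 0.01, pop, seed = 2)
  expect_lt(mean(tr$open) / pop$N_K, 1e-6)
  expect_gt(mean(tr$N0) / pop$N_K, 0.999)
})

test_that("current conversion follows Ohm's law per open channel", {
  pop <- channel_population()
  tr <- data.frame(time_ms = 0:2, N0 = c(9000L, 8999L, 9000L),
                   open = c(0L, 1L, 0L))
  attr(tr, "population") <- pop
  i <- fluctuating_current(tr, 55, pop)
  expect_equal(i, c(0, 20 * 67 * 1e-3, 0))    # one open channel: 1.34 pA
  expect_equal(fluctuating_current(tr, -12, pop), c(0, 0, 0))  # V = VK
  expect_error(fluctuating_current(tr, rep(5, 10), pop), "grid")
})

test_that("dt guard rejects steps that break the frozen-rate assumption", {
  expect_error(simulate_markov("n4", rep(55, 10), 0.2,
                               channel_population(), seed = 1),
               "reduce dt")
})

test_that("the periodogram estimator satisfies Parseval on white noise", {
  set.seed(42)
  dt <- 0.01
  traces <- lapply(1:4, function(i) rnorm(20000, sd = 3))
  ps <- empirical_psd(traces, dt)
  df <- 1 / (20000 * dt * 1e-3)
  expect_equal(sum(ps$psd) * df, 9, tolerance = 0.05)
  expect_equal(mean(ps$psd), 2 * 9 * dt * 1e-3, tolerance = 0.05)
  expect_error(empirical_psd(list(rnorm(10), rnorm(11)), dt), "equal length")
})

test_that("the stimulus does not alter the fluctuation spectrum", {
  pop <- channel_population()
  stim <- stimulus_spec(canonical_multipliers(), amplitude_mV = 0.25,
                        seed = 5)
  ps0 <- markov_psd("p2", 55, pop, iterations = 4, seed = 60)
  ps1 <- markov_psd("p2", 55, pop, iterations = 4, seed = 80,
                    stimulus = stim)
  ex <- stimulus_line_frequencies(canonical_multipliers())
  ana <- function(f) p2_psd(f, 55, pop)$S_total
  # 4 iterations x >= 3 Fourier bins per log bin: ~3.5 sigma of the log10
  # sampling scatter is 0.45
  d0 <- attr(psd_bin_compare(ps0, ana, nbins = 5), "max_abs_dlog10")
  d1 <- attr(psd_bin_compare(ps1, ana, nbins = 5, exclude_f = ex),
             "max_abs_dlog10")
  expect_lt(d0, 0.45)
  expect_lt(d1, 0.45)
})
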