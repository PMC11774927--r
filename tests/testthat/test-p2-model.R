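test_that("p2 rate constants are tied to the potassium gate rates", {
  V <- c(5, 30, 55)
  rn <- hh_gate_rates(V, "n")
  r <- p2_rates(V, A = 0.35, B = 4)
  expect_equal(r$k1, 0.35 * rn$alpha)
  expect_equal(r$k2, rn$beta)
  expect_equal(r$k3, rn$alpha)
  expect_equal(r$k4, 4 * rn$beta)
  expect_equal(r$a11, -(r$k1 + r$k2 + r$k3))
  expect_true(all(r$a21 > 0) && all(r$a22 < 0))
  # n^2 special case
  r2 <- p2_rates(V, A = 2, B = 2)
  expect_equal(r2$k1, 2 * rn$alpha)
  expect_equal(r2$k4, 2 * rn$beta)
  expect_error(p2_rates(5, A = 0), "positive")
  expect_error(p2_rates(5, B = -1), "positive")
})

test_that("steady state matches the sequential closed form and n^2 limit", {
  V <- setdiff(seq(-5, 100, by = 2.5), 10)  # alpha_n(10) = 0: boundary case
  ss <- p2_steady_state(V, 0.35, 4)
  r <- p2_rates(V, 0.35, 4)
  chain <- r$k1 * r$k3 / (r$k2 * r$k4 + r$k1 * r$k4 + r$k1 * r$k3)
  expect_equal(ss$p2_inf, chain, tolerance = 1e-12)
  expect_true(all(ss$p0_inf > 0 & ss$p1_inf > 0 & ss$p2_inf > 0))
  # matrix-inverse route, cross-checked with solve()
  for (v in c(5, 55)) {
    rr <- p2_rates(v, 0.35, 4)
    M <- matrix(c(rr$a11, rr$a12, rr$a21, rr$a22), 2, 2, byrow = TRUE)
    p <- solve(M, c(rr$a22 + rr$a12, 0))
    s <- p2_steady_state(v, 0.35, 4)
    expect_equal(c(s$p1_inf, s$p2_inf), p, tolerance = 1e-12)
  }
  ssn <- p2_steady_state(V, 2, 2)
  expect_equal(ssn$p2_inf, hh_gate_rates(V, "n")$x_inf^2, tolerance = 1e-12)
})

test_that("the reduced 2-variable system reproduces the 3-state master equation", {
  V0 <- 55
  dt <- 0.002
  nt <- 30000   # 60 ms ~ 10 relaxation times at 55 mV
  k <- p2_rates(V0)
  # independent oracle: Euler on the full 3x3 generator
  G <- matrix(c(-k$k1, k$k2, 0,
                k$k1, -(k$k2 + k$k3), k$k4,
                0, k$k3, -k$k4), 3, 3, byrow = TRUE)
  p <- c(1, 0, 0)
  oracle <- matrix(NA_real_, nt, 3)
  for (i in seq_len(nt)) { oracle[i, ] <- p; p <- p + dt * as.vector(G %*% p) }
  ss0 <- p2_steady_state(V0)
  tr <- integrate_voltage_clamp("p2", rep(V0, nt), dt, init = c(0, 0))
  expect_lt(max(abs(tr$p1 - oracle[, 2])), 1e-10)
  expect_lt(max(abs(tr$p2 - oracle[, 3])), 1e-10)
  expect_lt(max(abs(tr$p0 + tr$p1 + tr$p2 - 1)), 1e-12)
  expect_equal(tail(tr$p2, 1), ss0$p2_inf, tolerance = 1e-4)
})

test_that("eigensystem satisfies Vieta, the n^2 limit and frozen reference values", {
  for (v in seq(-5, 100, by = 5)) {
    es <- p2_eigensystem(v)
    expect_equal(es$lambda1 + es$lambda2, es$trace_T, tolerance = 1e-12)
    expect_equal(es$lambda1 * es$lambda2, es$det_D, tolerance = 1e-12)
    expect_true(es$lambda1 < 0 && es$lambda2 < es$lambda1)
    expect_equal(es$c1 + es$c2, 1 - es$p2_inf, tolerance = 1e-12)
  }
  # n^2 limit: relaxation times tau_n and tau_n / 2 exactly
  for (v in seq(-5, 100, by = 5)) {
    es <- p2_eigensystem(v, A = 2, B = 2)
    taun <- hh_gate_rates(v, "n")$tau
    expect_equal(es$tau1_ms, taun, tolerance = 1e-10)
    expect_equal(es$tau2_ms, taun / 2, tolerance = 1e-10)
    # binomial weights of [n + (1-n) e^(-t/tau)]^2 - n^2
    n <- hh_gate_rates(v, "n")$x_inf
    expect_equal(es$c1, 2 * n * (1 - n), tolerance = 1e-10)
    expect_equal(es$c2, (1 - n)^2, tolerance = 1e-10)
  }
  es55 <- p2_eigensystem(55)
  expect_equal(es55$lambda1, -0.1689158, tolerance = 1e-6)
  expect_equal(es55$lambda2, -0.7596791, tolerance = 1e-6)
})
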