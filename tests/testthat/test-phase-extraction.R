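make_stack <- function(times, values) {
  ts_stack(times, values, grid_locations(1, ncol(as.matrix(values))),
           kind = "intensity")
}

test_that("HP detrending is exact on polynomial-degree-one baselines", {
  t <- seq(0, 72, by = 0.5)
  lin <- make_stack(t, cbind(2 + 0.3 * t, rep(5, length(t))))
  for (lam in c(1, 1e4, 1e8)) {
    res <- hp_detrend(lin, smoothing = lam)
    # zero up to the conditioning of the (I + lambda D'D) solve
    expect_lt(max(abs(res$values)), 1e-5)
  }
})

test_that("HP detrending recovers a sinusoid over a drifting baseline", {
  t <- seq(0, 144, by = 0.5)
  s <- cos(2 * pi * t / 24)
  raw <- make_stack(t, cbind(s + 10 + 0.05 * t))
  det <- hp_detrend(raw)  # circadian default lambda
  interior <- t > 24 & t < 120
  relerr <- abs(det$values[interior, 1] - s[interior]) / max(abs(s))
  expect_lt(max(relerr), 0.05)
  # oracle: literal dense quadratic-program solution of the HP objective
  lam <- attr(det, "smoothing")
  T_ <- length(t)
  D2 <- diff(diag(T_), differences = 2)
  tau <- solve(diag(T_) + lam * crossprod(D2), raw$values[, 1])
  expect_equal(det$values[, 1], raw$values[, 1] - tau, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("HP filter limit lambda -> 0 gives vanishing residuals", {
  set.seed(4)
  t <- seq(0, 48, by = 0.5)
  noisy <- make_stack(t, cbind(rnorm(length(t))))
  res <- hp_detrend(noisy, smoothing = 1e-10)
  expect_lt(max(abs(res$values)), 1e-6)
  expect_error(hp_detrend(make_stack(c(0, 1, 3, 7), cbind(1:4, 2:5))),
               "uniform")
})

test_that("the analytic signal recovers phase and amplitude of cosines", {
  t <- seq(0, 240, by = 0.5)
  for (A in c(1, 3)) {
    st <- ts_stack(t, cbind(A * cos(2 * pi * t / 24)), grid_locations(1, 1),
                   "detrended")
    pa <- analytic_signal(st)
    interior <- t >= 24 & t <= 216  # one period from each edge
    expect_lt(max(abs(pa$amplitude$values[interior, 1] - A)) / A, 0.02)
    planted <- wrap_phase(2 * pi * t / 24)
    err <- abs(wrap_phase(pa$phase$values[interior, 1] - planted[interior]))
    expect_lt(max(err), 0.02 * 2 * pi)
    expect_true(all(pa$phase$values > -pi & pa$phase$values <= pi))
  }
  # edge flags cover the first and last 12 h
  st <- ts_stack(t, cbind(cos(2 * pi * t / 24)), grid_locations(1, 1), "detrended")
  em <- attr(analytic_signal(st)$phase, "edge_mask")
  expect_true(all(em[t < 12]) && all(em[t > 228]))
  expect_false(any(em[t >= 12 & t <= 228]))
  expect_error(
    analytic_signal(ts_stack(t, cbind(0 * t), grid_locations(1, 1), "detrended")),
    "undefined phase")
})

test_that("unwrapped phase of a chirp is monotone increasing", {
  t <- seq(0, 200, by = 0.5)
  inst <- 2 * pi * (t / 30 + t^2 / 8000)  # slowly increasing frequency
  st <- ts_stack(t, cbind(cos(inst)), grid_locations(1, 1), "detrended")
  ph <- analytic_signal(st)$phase$values[, 1]
  interior <- t > 20 & t < 180
  expect_true(all(diff(unwrap_phase(ph[interior])) > 0))
})

test_that("the Kuramoto order parameter matches its closed-form anchors", {
  expect_equal(kuramoto_order(rep(1.1, 7))$R, 1, tolerance = 1e-12)
  even <- kuramoto_order(seq(-pi, pi, length.out = 9)[-1])
  expect_lt(even$R, 1e-12)
  anti <- kuramoto_order(c(0, pi))
  expect_lt(anti$R, 1e-12)
  expect_false(anti$psi_defined)
  expect_true(is.na(anti$psi))
  # R = 1 iff all phases equal
  set.seed(1)
  th <- runif(50, -pi, pi)
  expect_lt(kuramoto_order(th)$R, 1 - 1e-12)
  expect_equal(kuramoto_order(th)$psi_defined, TRUE)
})

test_that("order traces aggregate R(t) over a phase stack", {
  t <- 0:10
  const <- ts_stack(t, matrix(0.4, 11, 6), grid_locations(2, 3), "phase")
  expect_true(all(order_trace(const)$R == 1))
  single <- ts_stack(t, matrix(runif(11, -pi, pi), 11, 1),
                     grid_locations(1, 1), "phase")
  expect_true(all(order_trace(single)$R == 1))
  # independently drifting phases: time-averaged R at the 1/sqrt(N) scale
  set.seed(6)
  N <- 400
  drift <- ts_stack(0:199, matrix(runif(200 * N, -pi, pi), 200, N),
                    grid_locations(20, 20), "phase")
  Rbar <- mean(order_trace(drift)$R)
  expect_lt(Rbar, 3 / sqrt(N))
  expect_gt(Rbar, 0.2 / sqrt(N))
})
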