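test_that("binary grid archetypes land where Moran's I says they should", {
  W <- grid_von_neumann_weights(10, 10, 1)
  expect_equal(morans_i(binary_grid(10, 10, "checkerboard"), W)$statistic, -1)
  blocks <- morans_i(binary_grid(10, 10, "blocks", seed = 1), W)$statistic
  expect_gt(blocks, 0.7)  # two homogeneous half-planes: close to +1
  # random fields stay inside the 95% band in >= 90% of seeds
  nd <- null_distribution(binary_grid(10, 10, "random", seed = 1), W,
                          "resample", 2000, seed = 99)
  band <- critical_band(nd, 0.05)
  inside <- vapply(1:30, function(s) {
    I <- morans_i(binary_grid(10, 10, "random", seed = s), W)$statistic
    I >= band["lower"] && I <= band["upper"]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
  # seed determinism
  expect_identical(binary_grid(6, 6, "random", seed = 4)$values,
                   binary_grid(6, 6, "random", seed = 4)$values)
})

test_that("phase patterns realize their archetypes", {
  Ws <- grid_von_neumann_weights(25, 25, 1)
  spiral <- phase_pattern(25, 25, "spiral")
  expect_lt(kuramoto_order(spiral$values)$R, 0.2)
  expect_gt(morans_i_circular(spiral, Ws)$statistic, 0.5)
  expect_error(phase_pattern(5, 5, "spiral", center = c(2, 2)),
               "lattice node")
  # long-wavelength plane wave: I-theta near its maximum, R not low
  wave <- phase_pattern(10, 10, "plane_wave", k = c(2 * pi / 100, 0))
  W10 <- grid_von_neumann_weights(10, 10, 1)
  expect_gt(morans_i_circular(wave, W10)$statistic, 0.85)
  expect_gt(kuramoto_order(wave$values)$R, 0.5)
  # random uniform phases: inside the null band in >= 90% of seeds
  nd <- null_distribution(phase_pattern(10, 10, "random", seed = 1), W10,
                          "resample", 2000, seed = 100)
  band <- critical_band(nd, 0.05)
  inside <- vapply(1:30, function(s) {
    f <- phase_pattern(10, 10, "random", seed = s)
    I <- morans_i_circular(f, W10)$statistic
    I >= band["lower"] && I <= band["upper"]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
  # two-cluster ground truth is attached
  tc <- phase_pattern(8, 8, "two_cluster", seed = 2)
  expect_equal(sort(unique(attr(tc, "cluster"))), 1:2)
  expect_equal(length(attr(tc, "cluster_means")), 2)
})

test_that("synthetic movies carry uniform sampling and ground truth", {
  mv <- synthetic_movie(4, 4, cluster_map = rep(1:2, each = 8),
                        cluster_phases = c(0, 1), noise_sd = 0.2,
                        baseline = list(offset = 3, slope = -0.01, decay = 0.01),
                        seed = 6)
  expect_equal(diff(mv$times), rep(0.5, length(mv$times) - 1))
  expect_equal(attr(mv, "true_phase_offset"),
               wrap_phase(c(0, 1)[rep(1:2, each = 8)]))
  expect_error(synthetic_movie(2, 2, duration = 30), "2 periods")
  # one-cluster movie: coherent at every time, I-theta high with
  # inverse-distance weights
  one <- synthetic_movie(4, 4, noise_sd = 0.02, seed = 7)
  pa <- analytic_signal(hp_detrend(one))
  tr <- order_trace(pa$phase)
  interior <- !attr(pa$phase, "edge_mask")
  expect_true(all(tr$R[interior] > 0.95))
})

test_that("the noise-free movie pipeline recovers planted phases", {
  mv <- synthetic_movie(5, 5, noise_sd = 0,
                        baseline = list(offset = 2, slope = -0.005, decay = 0.01),
                        seed = 1)
  pa <- analytic_signal(hp_detrend(mv))
  interior <- which(mv$times > 24 & mv$times < max(mv$times) - 24)
  planted <- wrap_phase(outer(2 * pi * mv$times[interior] / 24,
                              attr(mv, "true_phase_offset"), "+"))
  err <- abs(wrap_phase(pa$phase$values[interior, ] - planted))
  expect_lt(max(err), 0.05)
})

test_that("two-cluster movies yield recoverable cluster separations", {
  seeds <- 1:20
  errs <- vapply(seeds, function(s) {
    set.seed(s)
    cl <- sample(1:2, 100, replace = TRUE)
    mv <- synthetic_movie(10, 10, cluster_map = cl,
                          cluster_phases = c(0, 1.93), noise_sd = 0.05,
                          baseline = list(offset = 1, slope = 0, decay = 0.01),
                          seed = s + 500)
    pa <- analytic_signal(hp_detrend(mv))
    ph <- pa$phase$values[which.min(abs(mv$times - 72)), ]
    fit <- fit_bimodal_von_mises(ph, seed = s)
    abs(fit$delta_mu - 1.93)
  }, numeric(1))
  expect_lt(max(errs), 0.2)
})
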