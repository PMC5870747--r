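test_that("Moran's I reproduces its textbook anchor values", {
  W <- grid_von_neumann_weights(10, 10, 1)
  checker <- binary_grid(10, 10, "checkerboard")
  expect_equal(morans_i(checker, W)$statistic, -1, tolerance = 1e-14)
  # 2x2 grid with values [[1,1],[0,0]]: the four adjacent-pair deviation
  # products cancel, I = 0
  f <- spatial_field(c(1, 1, 0, 0), grid_locations(2, 2))
  expect_equal(morans_i(f, grid_von_neumann_weights(2, 2, 1))$statistic, 0)
  expect_error(morans_i(spatial_field(rep(3, 4), grid_locations(2, 2)),
                        grid_von_neumann_weights(2, 2, 1)),
               "degenerate")
  expect_error(morans_i(f, W), "units")
})

test_that("circular distance and mean follow the atan2 conventions", {
  expect_equal(circular_distance(pi, -pi + 0.01), -0.01)
  expect_equal(circular_distance(pi / 2, 0), pi / 2)
  for (x in c(-3, -0.5, 0, 1.2, pi)) {
    expect_equal(circular_distance(x, x), 0)
  }
  expect_true(all(abs(circular_distance(runif(100, -10, 10),
                                        runif(100, -10, 10))) <= pi))
  expect_equal(circular_mean(c(0, pi / 2)), pi / 4)
  expect_equal(circular_mean(c(1.3, 1.3)), 1.3)
  expect_error(circular_mean(c(-pi / 2, pi / 2)), "undefined circular mean")
})

test_that("circular Moran's I reduces to the scalar case on binary phase structure", {
  W <- grid_von_neumann_weights(10, 10, 1)
  checker <- binary_grid(10, 10, "checkerboard")
  # phases {0, pi/2}: circular mean pi/4, deviations +/- pi/4, same
  # alternating structure as the binary checkerboard
  pf <- phase_field(ifelse(checker$values == 1, pi / 2, 0), checker$locs)
  res <- morans_i_circular(pf, W)
  expect_equal(res$statistic, -1, tolerance = 1e-12)
  expect_equal(res$statistic, circmoran:::.moran_loop(pf$values, dense_w(W), circular = TRUE),
               tolerance = 1e-12)
  expect_error(morans_i_circular(phase_field(rep(0.7, 4), grid_locations(2, 2)),
                                 grid_von_neumann_weights(2, 2, 1)),
               "zero circular variance")
  # anti-phase field: circular mean undefined, no statistic is guessed
  expect_error(morans_i_circular(
    phase_field(rep(c(0, pi), 8), grid_locations(4, 4)),
    grid_von_neumann_weights(4, 4, 1)), "undefined circular mean")
})

test_that("vectorized I and I-theta match literal double-loop oracles", {
  for (s in 1:25) {
    n <- sample(5:100, 1)
    locs <- rand_free_locs(n, s)
    W <- inverse_distance_weights(locs, 1)
    f <- rand_scalar_field(n, s + 100)
    f$locs <- locs
    expect_equal(morans_i(f, W)$statistic,
                 circmoran:::.moran_loop(f$values, dense_w(W)), tolerance = 1e-12)
    pf <- rand_phase_field(n, s + 200)
    pf$locs <- locs
    expect_equal(morans_i_circular(pf, W)$statistic,
                 circmoran:::.moran_loop(pf$values, dense_w(W), circular = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I is affine invariant and symmetrization invariant", {
  for (s in 1:10) {
    f <- rand_scalar_field(30, s)
    W <- inverse_distance_weights(f$locs, 1)
    I0 <- morans_i(f, W)$statistic
    a <- runif(1, 0.1, 5) * sample(c(-1, 1), 1); b <- rnorm(1, 0, 10)
    g <- spatial_field(a * f$values + b, f$locs)
    expect_equal(morans_i(g, W)$statistic, I0, tolerance = 1e-12)
    # asymmetric weights: I(W) == I((W + W')/2)
    Wa <- W; Wa$W <- W$W * matrix(runif(30 * 30, 0, 2), 30)
    Wa$W <- methods::as(Wa$W, "CsparseMatrix")
    Ws <- Wa; Ws$W <- (Wa$W + Matrix::t(Wa$W)) / 2
    expect_equal(morans_i(f, Wa)$statistic, morans_i(f, Ws)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("I-theta is invariant under global phase rotation", {
  set.seed(11)
  for (s in 1:10) {
    pf <- phase_pattern(8, 8, "two_cluster", seed = s)
    W <- grid_von_neumann_weights(8, 8, 1)
    I0 <- morans_i_circular(pf, W)$statistic
    rot <- runif(1, -pi, pi)
    pf2 <- phase_field(pf$values + rot, pf$locs)
    expect_equal(morans_i_circular(pf2, W)$statistic, I0, tolerance = 1e-9)
  }
})

test_that("the average of I over all relabelings equals -1/(N-1) (N = 4 exhaustive)", {
  locs <- grid_locations(2, 2)
  W <- grid_von_neumann_weights(2, 2, 1)
  vals <- c(0.3, -1.2, 2.5, 0.9)
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  Is <- apply(perms, 1, function(p) {
    morans_i(spatial_field(vals[p], locs), W)$statistic
  })
  expect_equal(mean(Is), -1 / 3, tolerance = 1e-12)
})

test_that("correlograms decompose I over distance classes", {
  # single band covering all pairs equals I with all-ones weights
  f <- rand_scalar_field(20, 5)
  cg <- correlogram(f, c(0, 1e6))
  Wall <- inverse_distance_weights(f$locs, 0)
  expect_equal(cg$statistic[1], morans_i(f, Wall)$statistic, tolerance = 1e-12)
  # plane wave: I-theta decays from positive toward negative as the lag
  # approaches half the wavelength (64 cells -> lag 32)
  wave <- phase_pattern(1, 33, "plane_wave", k = c(2 * pi / 64, 0))
  cgw <- correlogram(wave, c(0.5, 1.5, 16.5, 32.5))
  expect_false(any(cgw$empty))
  expect_true(cgw$statistic[1] > 0.8)
  expect_true(all(diff(cgw$statistic) < 0))
  expect_true(cgw$statistic[3] < 0)
  # empty bands are flagged, not dropped
  cge <- correlogram(f, c(0, 1e5, 1e6))
  expect_true(cge$empty[2])
  expect_true(is.na(cge$statistic[2]))
  expect_equal(nrow(cge), 2)
})
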