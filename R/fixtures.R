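#' Binary grid test patterns
#'
#' The three archetypal binary 10 x 10 patterns used to build intuition for
#' Moran's I: `"blocks"` gives two homogeneous half-planes with a ragged
#' seed-drawn boundary (I close to +1), `"checkerboard"` strict parity
#' alternation (I = -1 under r = 1 von Neumann weights), and `"random"`
#' i.i.d. Bernoulli(p) cells (I near -1/(N-1)).
#'
#' @param rows,cols grid shape.
#' @param kind `"blocks"`, `"checkerboard"` or `"random"`.
#' @param p Bernoulli success probability for `"random"`.
#' @param seed integer seed for the stochastic kinds (`NULL` uses the
#'   current RNG stream).
#' @return a `spatial_field` on grid locations.
#' @export
binary_grid <- function(rows, cols, kind = c("checkerboard", "blocks", "random"),
                        p = 0.5, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(rows >= 1, cols >= 1)
  if (!is.null(seed)) set.seed(seed)
  locs <- grid_locations(rows, cols)
  r <- unclass(locs)[, "y"]; cc <- unclass(locs)[, "x"]
  values <- switch(kind,
    checkerboard = (r + cc) %% 2,
    blocks = {
      # vertical split with a +/- 1 column jitter per row
      split_at <- floor(cols / 2) + sample(c(-1L, 0L, 1L), rows, replace = TRUE)
      as.numeric(cc < split_at[r + 1])
    },
    random = stats::rbinom(rows * cols, 1, p))
  spatial_field(values, locs, label = paste0("binary_", kind))
}

#' Analytic and stochastic phase patterns
#'
#' Generators for the archetypal phase arrangements of oscillator
#' lattices: `"spiral"` (theta = atan2(y - y0, x - x0); spatially ordered
#' but globally incoherent, R near 0), `"plane_wave"` (theta = k . z +
#' phi0), `"random"` (uniform on the circle) and `"two_cluster"` (two von
#' Mises clusters separated by `delta_mu`, emulating the bimodal phase
#' distribution of long-photoperiod SCN tissue).
#'
#' @param rows,cols grid shape.
#' @param kind pattern kind.
#' @param center spiral center; default offsets it from lattice nodes
#'   (the phase is undefined exactly at the center).
#' @param k wave vector (rad per cell) for plane waves.
#' @param phi0 plane-wave phase offset.
#' @param delta_mu circular separation of the two cluster means (radians).
#' @param kappa von Mises concentration of each cluster.
#' @param weight mixing weight of the first cluster.
#' @param layout `"blocks"` (left/right halves) or `"random"` cluster
#'   assignment.
#' @param seed integer seed for the stochastic kinds.
#' @return a `phase_field`; stochastic kinds attach ground truth
#'   (`"cluster"` labels and `"cluster_means"`).
#' @export
phase_pattern <- function(rows, cols,
                          kind = c("spiral", "plane_wave", "random", "two_cluster"),
                          center = NULL, k = c(2 * pi / 10, 0), phi0 = 0,
                          delta_mu = 1.93, kappa = 8, weight = 0.5,
                          layout = c("blocks", "random"), seed = NULL) {
  kind <- match.arg(kind); layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  locs <- grid_locations(rows, cols)
  x <- unclass(locs)[, "x"]; y <- unclass(locs)[, "y"]
  if (kind == "spiral") {
    center <- center %||% c((cols - 1) / 2 + 0.21, (rows - 1) / 2 + 0.13)
    if (any(abs(x - center[1]) < 1e-12 & abs(y - center[2]) < 1e-12)) {
      stop("spiral center coincides with a lattice node: phase undefined there")
    }
    return(phase_field(atan2(y - center[2], x - center[1]), locs, "spiral"))
  }
  if (kind == "plane_wave") {
    return(phase_field(k[1] * x + k[2] * y + phi0, locs, "plane_wave"))
  }
  if (kind == "random") {
    return(phase_field(stats::runif(rows * cols, -pi, pi), locs, "random"))
  }
  # two_cluster
  n <- rows * cols
  mus <- wrap_phase(c(0, delta_mu))
  cluster <- if (layout == "blocks") as.integer(x >= cols / 2) + 1L
             else sample(1:2, n, replace = TRUE, prob = c(weight, 1 - weight))
  ph <- numeric(n)
  for (g in 1:2) {
    idx <- cluster == g
    ph[idx] <- rvonmises(sum(idx), mus[g], kappa)
  }
  out <- phase_field(ph, locs, "two_cluster")
  attr(out, "cluster") <- cluster
  attr(out, "cluster_means") <- mus
  out
}

#' Synthetic oscillatory movie
#'
#' Generates an SCN-like bioluminescence recording on a ROI grid: each
#' unit oscillates as amplitude * cos(2 pi t / period + phi_i) around a
#' baseline with offset, linear slope and exponential rundown
#' (offset * exp(-decay t) + slope * t), plus i.i.d. Gaussian noise. The
#' per-unit phase offsets phi_i come from `cluster_phases[cluster_map]`,
#' so one- or two-cluster tissues are both expressible. Planted
#' ground-truth phase offsets are attached for recovery tests.
#'
#' @param rows,cols ROI grid shape.
#' @param cluster_map integer vector (length rows * cols, row-major) of
#'   cluster labels; default all 1.
#' @param cluster_phases phase offset (radians) per cluster label.
#' @param period_h oscillation period (hours).
#' @param amplitude oscillation amplitude.
#' @param noise_sd Gaussian noise s.d. (>= 0).
#' @param baseline list with `offset`, `slope` (per hour) and `decay`
#'   (1/hours) of the baseline drift.
#' @param dt sampling interval (hours).
#' @param duration recording length (hours); at least 2 periods.
#' @param seed integer seed.
#' @return a `ts_stack` of kind `"intensity"` with attributes
#'   `"true_phase_offset"` (phi_i per unit) and `"cluster_map"`.
#' @export
synthetic_movie <- function(rows, cols, cluster_map = NULL, cluster_phases = 0,
                            period_h = 24, amplitude = 1, noise_sd = 0,
                            baseline = list(offset = 0, slope = 0, decay = 0),
                            dt = 0.5, duration = 144, seed = NULL) {
  stopifnot(noise_sd >= 0, dt > 0)
  if (duration < 2 * period_h) stop("duration must cover at least 2 periods")
  if (!is.null(seed)) set.seed(seed)
  n <- rows * cols
  cluster_map <- cluster_map %||% rep(1L, n)
  if (length(cluster_map) != n) stop("cluster_map must have rows * cols labels")
  phi <- wrap_phase(cluster_phases[cluster_map])
  times <- seq(0, duration, by = dt)
  base <- baseline$offset * exp(-baseline$decay * times) +
    baseline$slope * times
  osc <- outer(2 * pi * times / period_h, phi, "+")
  values <- base + amplitude * cos(osc)
  if (noise_sd > 0) {
    values <- values + matrix(stats::rnorm(length(values), 0, noise_sd),
                              nrow = length(times))
  }
  out <- ts_stack(times, values, grid_locations(rows, cols), "intensity")
  attr(out, "true_phase_offset") <- phi
  attr(out, "cluster_map") <- cluster_map
  out
}
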