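#' Sample intrinsic oscillator frequencies from a period distribution
#'
#' Intrinsic periods tau_i are drawn from Normal(mean_h, sd_h), matching
#' the period dispersal of uncoupled single SCN neurons (24 +/- ~2 h), and
#' converted to angular frequencies omega_i = 2 pi / tau_i. Draws are
#' truncated below at 1 h to exclude pathological near-zero or negative
#' periods from the normal tail; the parameter guard mean - 5 sd > 0 keeps
#' that truncation an extreme-tail event.
#'
#' @param n number of oscillators.
#' @param mean_h,sd_h period mean and standard deviation (hours).
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @return numeric vector of omega_i (rad/h) with the sampled periods
#'   attached as attribute `"periods"`.
#' @export
sample_periods <- function(n, mean_h = 24, sd_h = 2, seed = NULL) {
  stopifnot(n >= 1, mean_h > 0, sd_h >= 0)
  if (!(mean_h - 5 * sd_h > 0)) {
    stop("period distribution too wide: require mean_h - 5 * sd_h > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  tau <- stats::rnorm(n, mean_h, sd_h)
  while (any(tau <= 1)) {
    tau[tau <= 1] <- stats::rnorm(sum(tau <= 1), mean_h, sd_h)
  }
  structure(2 * pi / tau, periods = tau)
}

#' Simulate a two-dimensional Kuramoto oscillator lattice
#'
#' Integrates the coupled phase equations
#' \deqn{\dot\theta_i = \omega_i + K \sum_{j \in N_1(i)} \sin(\theta_j - \theta_i)}
#' on a rows x cols lattice from uniform-random initial phases.
#' `coupling = "nearest"` sums over the range-1 von Neumann neighbors with
#' open boundaries (edge oscillators have 2-3 neighbors, as in a finite
#' tissue); `coupling = "mean_field"` uses (K/N) sum_j sin(theta_j -
#' theta_i), the N-normalization keeping K intensive and comparable across
#' lattice sizes. Integration runs on unwrapped phases with an
#' adaptive-step solver; phases are wrapped to (-pi, pi] only at output.
#' The seed fixes both the intrinsic frequencies and the initial phases,
#' so identical configurations give identical results.
#'
#' @param rows,cols lattice dimensions (rows * cols >= 4).
#' @param K coupling strength (may be negative: phase-repulsive coupling).
#' @param coupling `"nearest"` or `"mean_field"`.
#' @param period_mean,period_sd intrinsic period distribution (hours).
#' @param t_end integration horizon in hours (default 2400 = 100 days).
#' @param dt_out output cadence in hours (default 0.5 h, the typical
#'   bioluminescence sampling interval).
#' @param seed integer seed for frequencies and initial phases.
#' @param rtol,atol integrator tolerances.
#' @return a `sim_result`: `times`, `theta` (T x N wrapped phases),
#'   `omega`, `config`, and the von Neumann `weights` used for nearest
#'   coupling.
#' @export
simulate_lattice <- function(rows, cols, K,
                             coupling = c("nearest", "mean_field"),
                             period_mean = 24, period_sd = 2,
                             t_end = 2400, dt_out = 0.5, seed = 1,
                             rtol = 1e-6, atol = 1e-8) {
  coupling <- match.arg(coupling)
  N <- rows * cols
  stopifnot(N >= 4, t_end > 0, dt_out > 0)
  set.seed(seed)
  omega <- sample_periods(N, period_mean, period_sd, seed = NULL)
  theta0 <- stats::runif(N, -pi, pi)
  Wvn <- grid_von_neumann_weights(rows, cols, 1)
  A <- Wvn$W
  deriv <- if (coupling == "nearest") {
    function(t, th, parms) {
      s <- sin(th); cth <- cos(th)
      list(omega + K * (cth * as.numeric(A %*% s) - s * as.numeric(A %*% cth)))
    }
  } else {
    function(t, th, parms) {
      s <- sin(th); cth <- cos(th)
      list(omega + (K / N) * (cth * sum(s) - s * sum(cth)))
    }
  }
  times <- seq(0, t_end, by = dt_out)
  out <- tryCatch(
    deSolve::ode(theta0, times, deriv, NULL, method = "adams",
                 rtol = rtol, atol = atol),
    error = function(e) stop(sprintf(
      "integrator failure (rtol = %g, atol = %g): %s", rtol, atol,
      conditionMessage(e)))
  )
  if (nrow(out) < length(times)) {
    stop(sprintf("integrator failure at t = %g h (rtol = %g, atol = %g)",
                 out[nrow(out), 1], rtol, atol))
  }
  theta <- wrap_phase(out[, -1, drop = FALSE])
  structure(list(times = times, theta = theta, omega = as.numeric(omega),
                 weights = Wvn,
                 config = list(rows = rows, cols = cols, K = K,
                               coupling = coupling, period_mean = period_mean,
                               period_sd = period_sd, t_end = t_end,
                               dt_out = dt_out, seed = seed,
                               rtol = rtol, atol = atol)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sim_result: %dx%d lattice, K = %g (%s), t = %g h, seed = %d>\n",
              cfg$rows, cfg$cols, cfg$K, cfg$coupling, cfg$t_end, cfg$seed))
  invisible(x)
}

#' Phase stack view of a simulation
#' @param sim a `sim_result`.
#' @return a `ts_stack` of kind `"phase"`.
#' @export
sim_phase_stack <- function(sim) {
  ts_stack(sim$times, sim$theta, sim$weights$locs, "phase")
}

#' Per-time Moran I-theta and Kuramoto R of a simulation
#'
#' Evaluates the circular Moran statistic and the order parameter at every
#' output time; when a null distribution is supplied, each time point is
#' flagged significant if I-theta falls outside the null's two-sided
#' critical band. Degenerate phase fields at isolated times (fully
#' synchronized, or undefined circular mean) yield NA and a flag rather
#' than an error.
#'
#' @param sim a `sim_result`.
#' @param W a `weight_matrix` matching the lattice (default: the
#'   simulation's own r = 1 von Neumann weights).
#' @param null optional `null_distribution` for the band flags.
#' @param alpha significance level for the band.
#' @return data.frame `time`, `I_theta`, `R`, `degenerate`, `significant`.
#' @export
trajectory_metrics <- function(sim, W = NULL, null = NULL, alpha = 0.05) {
  W <- W %||% sim$weights
  if (nrow(W$W) != ncol(sim$theta)) {
    stop("weight matrix does not match the lattice geometry")
  }
  S0 <- total_weight(W)
  Tn <- nrow(sim$theta)
  I <- rep(NA_real_, Tn); R <- rep(NA_real_, Tn)
  for (k in seq_len(Tn)) {
    th <- sim$theta[k, ]
    R[k] <- Mod(mean(exp(1i * th)))
    I[k] <- tryCatch({
      mu <- circular_mean(th)
      d <- circular_distance(th, mu)
      if (sum(d^2) <= 0) NA_real_ else .moran_stat(d, W$W, S0)
    }, error = function(e) NA_real_)
  }
  out <- data.frame(time = sim$times, I_theta = I, R = R,
                    degenerate = !is.finite(I))
  if (!is.null(null)) {
    band <- critical_band(null, alpha, TRUE)
    out$significant <- !out$degenerate &
      (out$I_theta < band["lower"] | out$I_theta > band["upper"])
  }
  out
}

#' Steady-state (I-theta, R) summary of a simulation
#'
#' Time averages of I-theta(t) and R(t) over the tail of the trajectory,
#' after discarding the leading `discard_fraction` as transient dynamics.
#'
#' @param sim a `sim_result`.
#' @param W optional `weight_matrix` (default: the lattice's own).
#' @param discard_fraction fraction of the trajectory discarded as
#'   transient, in \[0, 1); must leave at least 10 output samples.
#' @return list `I_theta_inf`, `R_inf`, `n_retained`.
#' @export
steady_state_summary <- function(sim, W = NULL, discard_fraction = 0.5) {
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must lie in [0, 1)")
  }
  m <- trajectory_metrics(sim, W)
  keep <- seq_len(nrow(m)) > discard_fraction * nrow(m)
  if (sum(keep) < 10) stop("retained window too short (< 10 samples)")
  list(I_theta_inf = mean(m$I_theta[keep], na.rm = TRUE),
       R_inf = mean(m$R[keep]),
       n_retained = sum(keep))
}
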