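#' Hodrick-Prescott baseline detrending
#'
#' Removes the slow baseline drift of each unit's time series by
#' subtracting the Hodrick-Prescott trend, the minimizer of
#' \deqn{\sum_t (s_t - \tau_t)^2 + \lambda \sum_t (\tau_{t+1} - 2\tau_t + \tau_{t-1})^2.}
#' Linear (and constant) series incur zero curvature penalty, are fitted
#' exactly, and leave an identically zero residual for any lambda. The
#' default smoothing follows the period-scaled convention
#' lambda = 0.05 * (period / dt)^4 with a 24 h reference period, suitable
#' for circadian recordings; always user-overridable.
#'
#' @param stack a uniformly sampled `ts_stack`.
#' @param smoothing positive smoothing parameter lambda; `NULL` for the
#'   circadian default.
#' @return a `ts_stack` of kind `"detrended"` carrying the trend in
#'   attribute `"trend"`.
#' @export
hp_detrend <- function(stack, smoothing = NULL) {
  if (!inherits(stack, "ts_stack")) stop("stack must be a ts_stack")
  T_ <- length(stack$times)
  if (T_ < 4) stop("need at least 4 time points")
  dt <- stack_dt(stack)
  lambda <- smoothing %||% (0.05 * (24 / dt)^4)
  if (!(lambda > 0)) stop("smoothing must be positive")
  trend <- hp_trend(stack$values, lambda)
  out <- ts_stack(stack$times, stack$values - trend, stack$locs, "detrended")
  attr(out, "trend") <- trend
  attr(out, "smoothing") <- lambda
  out
}

# sparse banded solve of (I + lambda D2'D2) tau = s, all columns at once
hp_trend <- function(values, lambda) {
  T_ <- nrow(values)
  D2 <- Matrix::bandSparse(T_ - 2, T_, k = 0:2,
                           diagonals = list(rep(1, T_ - 2),
                                            rep(-2, T_ - 2),
                                            rep(1, T_ - 2)))
  M <- Matrix::Diagonal(T_) + lambda * Matrix::crossprod(D2)
  as.matrix(Matrix::solve(M, values))
}

#' Analytic-signal phase and amplitude
#'
#' Embeds each detrended series s(t) in the complex plane as
#' z(t) = s(t) + i H(s(t)) via the discrete (FFT) Hilbert transform;
#' the instantaneous phase is atan2(Im z, Re z) wrapped to (-pi, pi] and
#' the instantaneous amplitude is |z(t)|. The discrete transform suffers
#' edge effects; estimates within `edge_h` hours of either end are flagged
#' low-confidence via the `"edge_mask"` attribute (TRUE = edge) so that
#' downstream statistics can optionally exclude them.
#'
#' @param stack a `ts_stack` of kind `"detrended"` (zero-mean-ish signals).
#' @param edge_h width (hours) of the low-confidence window at each end.
#' @return list with `phase` and `amplitude` ts_stacks; both carry the
#'   `"edge_mask"` attribute.
#' @export
analytic_signal <- function(stack, edge_h = 12) {
  if (!inherits(stack, "ts_stack")) stop("stack must be a ts_stack")
  if (stack$kind != "detrended") {
    warning("analytic_signal expects a detrended stack; got kind '",
            stack$kind, "'")
  }
  stack_dt(stack)  # enforce uniform sampling
  allzero <- apply(stack$values, 2, function(x) all(x == 0))
  if (any(allzero)) {
    stop("undefined phase: unit(s) ", paste(which(allzero), collapse = ", "),
         " are identically zero")
  }
  z <- apply(stack$values, 2, hilbert_analytic)
  ph <- wrap_phase(atan2(Im(z), Re(z)))
  am <- Mod(z)
  edge <- stack$times < (stack$times[1] + edge_h) |
    stack$times > (stack$times[length(stack$times)] - edge_h)
  phase <- ts_stack(stack$times, ph, stack$locs, "phase")
  amplitude <- ts_stack(stack$times, am, stack$locs, "amplitude")
  attr(phase, "edge_mask") <- edge
  attr(amplitude, "edge_mask") <- edge
  list(phase = phase, amplitude = amplitude)
}

# discrete analytic signal via the one-sided spectrum: double positive
# frequencies, zero negative ones, keep DC (and Nyquist for even length)
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto order parameter of a phase set
#'
#' Modulus R and argument psi of the mean unit phasor
#' (1/N) sum_j exp(i theta_j): R = 1 means full phase coherence, R = 0
#' balanced cancellation (psi is then undefined and returned as NA with
#' `psi_defined = FALSE`).
#'
#' @param phases angles in radians.
#' @param tol modulus below which psi is reported undefined.
#' @return list with `R` in \[0, 1\], `psi` in (-pi, pi] (NA if undefined)
#'   and `psi_defined`.
#' @export
kuramoto_order <- function(phases, tol = 1e-12) {
  if (length(phases) < 1) stop("need at least one phase")
  z <- mean(exp(1i * phases))
  R <- min(Mod(z), 1)
  if (R < tol) list(R = R, psi = NA_real_, psi_defined = FALSE)
  else list(R = R, psi = wrap_phase(Arg(z)), psi_defined = TRUE)
}

#' Kuramoto order parameter over time
#'
#' Applies [kuramoto_order()] at every time point of a phase stack.
#'
#' @param stack a `ts_stack` of kind `"phase"`.
#' @return an `order_trace` data.frame with columns `time`, `R`, `psi`,
#'   `psi_defined`.
#' @export
order_trace <- function(stack) {
  if (!inherits(stack, "ts_stack") || stack$kind != "phase") {
    stop("order_trace needs a phase ts_stack")
  }
  res <- apply(stack$values, 1, kuramoto_order)
  out <- data.frame(time = stack$times,
                    R = vapply(res, `[[`, numeric(1), "R"),
                    psi = vapply(res, `[[`, numeric(1), "psi"),
                    psi_defined = vapply(res, `[[`, logical(1), "psi_defined"))
  class(out) <- c("order_trace", class(out))
  out
}

#' Unwrap a phase sequence
#'
#' Cumulative unwrapping of a sampled phase trajectory onto the real line
#' (diagnostic only: the Moran statistics and R are wrap-invariant and
#' never use unwrapped phases).
#'
#' @param phases wrapped phase sequence in time order.
#' @return unwrapped phases; first value unchanged.
#' @export
unwrap_phase <- function(phases) {
  if (length(phases) < 2) return(phases)
  cumsum(c(phases[1], wrap_phase(diff(phases))))
}
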