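#' Time-series stack
#'
#' A T x N matrix of per-unit time series (bioluminescence-like
#' intensities, detrended signals, phases or amplitudes) on a common,
#' uniformly sampled time grid, with per-unit 2-D locations.
#'
#' @param times strictly increasing numeric vector of T time points (hours).
#' @param values T x N numeric matrix, one column per spatial unit.
#' @param locs a `locations` object with N points.
#' @param kind one of `"intensity"`, `"detrended"`, `"phase"`, `"amplitude"`.
#' @return a `ts_stack` object.
#' @export
ts_stack <- function(times, values,
                     locs, kind = c("intensity", "detrended", "phase", "amplitude")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(times) != nrow(values)) stop("times and values rows disagree")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (ncol(values) != n_units(locs)) {
    stop(sprintf("values has %d units but locations %d", ncol(values), n_units(locs)))
  }
  structure(list(times = times, values = values, locs = locs, kind = kind),
            class = "ts_stack")
}

#' @export
print.ts_stack <- function(x, ...) {
  cat(sprintf("<ts_stack: %d time points x %d units, kind = %s, dt = %g h>\n",
              length(x$times), ncol(x$values), x$kind,
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  invisible(x)
}

# uniform sampling interval, erroring otherwise (needed by the discrete
# analytic-signal transform and the HP filter)
stack_dt <- function(stack, rel_tol = 1e-6) {
  dt <- diff(stack$times)
  if (length(dt) == 0) stop("stack has a single time point")
  if (max(abs(dt - dt[1])) > rel_tol * abs(dt[1])) {
    stop("non-uniform time grid: uniform sampling interval required")
  }
  dt[1]
}

#' Extract one time point of a stack as a field
#'
#' @param stack a `ts_stack`.
#' @param time time point (nearest grid time is used).
#' @return a `phase_field` for phase stacks, else a `spatial_field`.
#' @export
stack_slice <- function(stack, time) {
  k <- which.min(abs(stack$times - time))
  v <- stack$values[k, ]
  if (stack$kind == "phase") phase_field(v, stack$locs)
  else spatial_field(v, stack$locs)
}
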