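#' Signed circular distance between two angles
#'
#' The signed shortest angular displacement from `b` to `a` on the unit
#' circle, dtheta(a, b) = atan2(sin(a - b), cos(a - b)). Euclidean
#' differences fail on the circle (pi and -pi + eps are 2*pi - eps apart
#' arithmetically but eps apart on the circle); this distance does not.
#'
#' @param a,b angles in radians (vectorized, recycled).
#' @return signed displacement(s) in (-pi, pi].
#' @examples
#' circular_distance(pi, -pi + 0.01)  # -0.01, not 2*pi - 0.01
#' @export
circular_distance <- function(a, b) {
  wrap_phase(a - b)
}

#' Circular mean of a set of angles
#'
#' atan2 of the mean sine and mean cosine. Undefined when the resultant
#' vector (C-bar, S-bar) has length below `tol` (e.g. an antipodal pair),
#' in which case an error is raised rather than an arbitrary angle returned.
#'
#' @param phases angles in radians.
#' @param tol resultant-length tolerance below which the mean is undefined.
#' @return the mean direction in (-pi, pi].
#' @export
circular_mean <- function(phases, tol = 1e-9) {
  C <- mean(cos(phases)); S <- mean(sin(phases))
  if (sqrt(C^2 + S^2) <= tol) {
    stop("undefined circular mean: resultant length below tolerance ",
         "(e.g. antipodal or balanced phases)")
  }
  wrap_phase(atan2(S, C))
}

new_moran_result <- function(statistic, n, S0, variant) {
  structure(list(statistic = statistic, n_units = n, total_weight = S0,
                 variant = variant),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result: %s %s = %.6f, N = %d, S0 = %g>\n",
              if (x$variant == "circular") "I_theta" else "I",
              "", x$statistic, x$n_units, x$total_weight))
  invisible(x)
}

# core Moran ratio on a deviation vector: (N / (S0 * sum d^2)) * d' W d
.moran_stat <- function(d, W, S0 = sum(W)) {
  n <- length(d)
  ss <- sum(d^2)
  (n / (S0 * ss)) * as.numeric(Matrix::crossprod(d, W %*% d))
}

check_field_weights <- function(field, W) {
  n <- length(field$values)
  if (n != nrow(W$W)) {
    stop(sprintf("field has %d units but weight matrix indexes %d", n, nrow(W$W)))
  }
  S0 <- total_weight(W)
  if (!(S0 > 0)) stop("weight matrix has zero total weight (empty band?)")
  S0
}

#' Moran's I for a scalar spatial field
#'
#' The global spatial autocorrelation index
#' \deqn{I = \frac{N \sum_{ij} w_{ij} (X_i - \bar X)(X_j - \bar X)}
#'           {\sum_{ij} w_{ij} \cdot \sum_i (X_i - \bar X)^2},}
#' the ratio of neighborhood-weighted covariance to total variance: near +1
#' for locally coherent fields, -1 for locally alternating fields, and
#' -1/(N-1) in expectation for spatially random fields.
#'
#' @param field a [spatial_field()].
#' @param W a `weight_matrix` over the same N units.
#' @return a `moran_result` with the statistic, N and total weight S0.
#' @examples
#' f <- binary_grid(10, 10, "checkerboard")
#' W <- grid_von_neumann_weights(10, 10, 1)
#' morans_i(f, W)$statistic  # exactly -1
#' @export
morans_i <- function(field, W) {
  if (!inherits(field, "spatial_field")) stop("field must be a spatial_field")
  S0 <- check_field_weights(field, W)
  d <- field$values - mean(field$values)
  if (sum(d^2) <= 0) stop("degenerate field: zero variance, Moran's I undefined")
  new_moran_result(.moran_stat(d, W$W, S0), length(d), S0, "scalar")
}

#' Circular Moran's I for a phase field
#'
#' The circular-statistics variant of Moran's I for cyclic data such as
#' instantaneous phases: arithmetic deviations (X_i - X-bar) are replaced by
#' signed shortest angular distances dtheta(X_i, X-bar) to the circular
#' mean. Everything else is the standard Moran ratio.
#'
#' @param field a [phase_field()].
#' @param W a `weight_matrix` over the same N units.
#' @return a `moran_result` (variant `"circular"`).
#' @export
morans_i_circular <- function(field, W) {
  if (!inherits(field, "phase_field")) stop("field must be a phase_field")
  S0 <- check_field_weights(field, W)
  mu <- circular_mean(field$values)   # errors when undefined
  d <- circular_distance(field$values, mu)
  if (sum(d^2) <= 0) stop("degenerate phase field: zero circular variance")
  new_moran_result(.moran_stat(d, W$W, S0), length(d), S0, "circular")
}

# literal double-loop transcription of the Moran ratio; test oracle
.moran_loop <- function(values, Wdense, circular = FALSE) {
  n <- length(values)
  if (circular) {
    mu <- circular_mean(values)
    d <- vapply(values, function(v) circular_distance(v, mu), numeric(1))
  } else {
    d <- values - mean(values)
  }
  num <- 0; S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + Wdense[i, j] * d[i] * d[j]
    S0 <- S0 + Wdense[i, j]
  }
  (1 / S0) * num / (sum(d^2) / n)
}

#' Spatial correlogram over distance classes
#'
#' Computes the Moran statistic (scalar I or circular I depending on the
#' field type) in each half-open distance band (e_k, e_{k+1}] defined by
#' `bin_edges`, using [distance_band_weights()]. Empty bands are flagged,
#' not silently dropped; per-band degenerate-field errors propagate.
#'
#' @param field a `spatial_field` or `phase_field`.
#' @param bin_edges strictly increasing numeric vector (>= 2 values) of
#'   distance-class edges.
#' @return a data.frame with one row per band: `d_lo`, `d_hi`, `n_links`
#'   (nonzero weight entries), `statistic` (NA for empty bands) and `empty`.
#' @export
correlogram <- function(field, bin_edges) {
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be >= 2 strictly increasing values")
  }
  circular <- inherits(field, "phase_field")
  nb <- length(bin_edges) - 1
  out <- data.frame(d_lo = bin_edges[-length(bin_edges)],
                    d_hi = bin_edges[-1],
                    n_links = NA_integer_, statistic = NA_real_, empty = TRUE)
  for (k in seq_len(nb)) {
    W <- distance_band_weights(field$locs, out$d_lo[k], out$d_hi[k])
    out$n_links[k] <- Matrix::nnzero(W$W)
    if (isTRUE(W$meta$empty)) next
    res <- if (circular) morans_i_circular(field, W) else morans_i(field, W)
    out$statistic[k] <- res$statistic
    out$empty[k] <- FALSE
  }
  out
}
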