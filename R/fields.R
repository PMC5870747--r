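#' Wrap angles to the canonical phase interval
#'
#' Maps arbitrary angles (radians) to the canonical circular domain
#' (-pi, pi], the convention used throughout for instantaneous phases.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length with all values in (-pi, pi].
#' @examples
#' wrap_phase(c(0, 3 * pi, -pi))
#' @export
wrap_phase <- function(x) {
  r <- atan2(sin(x), cos(x))
  # atan2 can land on -pi for inputs an ulp below the branch cut
  r[r <= -pi] <- r[r <= -pi] + 2 * pi
  r
}

#' Construct grid locations
#'
#' Row-major 0-based (row, col) coordinates for a rows x cols lattice,
#' stored as (x = col, y = row). Unit cell spacing.
#'
#' @param rows,cols positive integer grid dimensions.
#' @return a `locations` object (two-column matrix with a `frame` attribute).
#' @export
grid_locations <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  g <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))
  locations(cbind(x = g$col, y = g$row), frame = "grid")
}

#' Construct free-plane or grid locations
#'
#' @param coords two-column matrix or data.frame of 2-D coordinates.
#' @param frame `"grid"` (integer row/col lattice) or `"free"` (real plane).
#' @return a `locations` object.
#' @export
locations <- function(coords, frame = c("free", "grid")) {
  frame <- match.arg(frame)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("locations must be 2-D (two columns)")
  if (!is.numeric(coords) || anyNA(coords)) stop("locations must be finite numeric")
  colnames(coords) <- c("x", "y")
  structure(coords, frame = frame, class = c("locations", class(coords)))
}

#' @export
print.locations <- function(x, ...) {
  cat(sprintf("<locations: %d points, frame = %s>\n", nrow(x), attr(x, "frame")))
  invisible(x)
}

n_units <- function(locs) nrow(locs)

#' Spatial field of scalar observations
#'
#' Bundles N real-valued observations with their 2-D locations; the input
#' object for scalar Moran's I.
#'
#' @param values numeric vector of N finite observations.
#' @param locs a `locations` object of matching length.
#' @param label free-text description.
#' @return a `spatial_field` object.
#' @seealso [phase_field()], [morans_i()]
#' @export
spatial_field <- function(values, locs, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a spatial field needs at least 2 units")
  if (!all(is.finite(values))) stop("spatial field values must be finite")
  if (length(values) != n_units(locs)) {
    stop(sprintf("values (%d) and locations (%d) disagree in length",
                 length(values), n_units(locs)))
  }
  structure(list(values = values, locs = locs, label = label),
            class = "spatial_field")
}

#' Phase field of circular observations
#'
#' N circular observations in radians, canonically wrapped to (-pi, pi] on
#' ingestion; the input object for the circular Moran statistic.
#'
#' @param phases numeric vector of N angles (radians; wrapped internally).
#' @param locs a `locations` object of matching length.
#' @param label free-text description.
#' @return a `phase_field` object.
#' @seealso [morans_i_circular()], [circular_mean()]
#' @export
phase_field <- function(phases, locs, label = "") {
  phases <- as.numeric(phases)
  if (length(phases) < 2) stop("a phase field needs at least 2 units")
  if (!all(is.finite(phases))) stop("phases must be finite")
  if (length(phases) != n_units(locs)) {
    stop(sprintf("phases (%d) and locations (%d) disagree in length",
                 length(phases), n_units(locs)))
  }
  structure(list(values = wrap_phase(phases), locs = locs, label = label),
            class = "phase_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("<spatial_field: %d units%s>\n", length(x$values),
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field: %d units%s>\n", length(x$values),
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}
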