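#' @importFrom Matrix sparseMatrix Diagonal crossprod colSums rowSums t
NULL

new_weight_matrix <- function(W, meta, locs = NULL) {
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  structure(list(W = W, meta = meta, locs = locs), class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix: %d units, %d nonzero entries, S0 = %g, kind = %s>\n",
              nrow(x$W), Matrix::nnzero(x$W), total_weight(x),
              x$meta$kind %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total weight S0 of a weight matrix
#' @param W a `weight_matrix`.
#' @return the scalar sum of all weights.
#' @export
total_weight <- function(W) sum(W$W)

#' Von Neumann lattice neighborhood weights
#'
#' Binary weights on a rows x cols grid: w_ij = 1 when cells i and j are
#' within Manhattan distance `range_r` of each other (and distinct), 0
#' otherwise. Open boundaries: edge cells simply have fewer neighbors.
#' Masked cells (no-tissue regions) are removed from the index space
#' entirely, so downstream statistics count only valid units.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param range_r neighborhood range r >= 1 (Manhattan metric).
#' @param mask optional logical rows x cols matrix; `TRUE` keeps a cell.
#' @return a `weight_matrix` over the kept cells, with their grid
#'   locations attached.
#' @examples
#' W <- grid_von_neumann_weights(10, 10, 1)
#' total_weight(W)  # 360 for the 10x10 rook lattice
#' @export
grid_von_neumann_weights <- function(rows, cols, range_r = 1, mask = NULL) {
  stopifnot(rows >= 1, cols >= 1, range_r >= 1)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), c(as.integer(rows), as.integer(cols)))) {
      stop("mask shape must match the grid")
    }
    keep <- as.vector(t(mask))       # row-major, matching grid_locations
  } else {
    keep <- rep(TRUE, rows * cols)
  }
  if (!any(keep)) stop("no usable units: mask excludes all cells")
  locs <- grid_locations(rows, cols)
  locs_kept <- locations(locs[keep, , drop = FALSE], frame = "grid")
  xy <- locs_kept
  n <- nrow(xy)
  # enumerate pairs within Manhattan range via offset stencil (row-major order)
  offs <- expand.grid(dy = -range_r:range_r, dx = -range_r:range_r)
  offs <- offs[abs(offs$dx) + abs(offs$dy) <= range_r &
                 !(offs$dx == 0 & offs$dy == 0), ]
  index <- matrix(NA_integer_, rows, cols)
  index[cbind(xy[, "y"] + 1, xy[, "x"] + 1)] <- seq_len(n)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nx <- xy[, "x"] + offs$dx[k]
    ny <- xy[, "y"] + offs$dy[k]
    ok <- nx >= 0 & nx < cols & ny >= 0 & ny < rows
    j <- rep(NA_integer_, n)
    j[ok] <- index[cbind(ny[ok] + 1, nx[ok] + 1)]
    ok <- ok & !is.na(j)
    ii <- c(ii, which(ok)); jj <- c(jj, j[ok])
  }
  if (length(ii) == 0 && n > 1) {
    W <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(n, n))
  } else {
    W <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  }
  new_weight_matrix(W,
    meta = list(kind = "von_neumann", rows = rows, cols = cols,
                range_r = range_r, masked = !is.null(mask)),
    locs = locs_kept)
}

#' Inverse-distance spatial weights
#'
#' w_ij = ||Z_i - Z_j||^(-alpha) for i != j, zero diagonal. The decay
#' parameter alpha sets the typical interaction range; alpha = 0 gives the
#' all-ones (off-diagonal) matrix, i.e. global coupling.
#'
#' @param locs a `locations` object with no coincident points.
#' @param alpha non-negative decay exponent.
#' @return a dense-support `weight_matrix`.
#' @export
inverse_distance_weights <- function(locs, alpha = 1) {
  stopifnot(alpha >= 0)
  n <- n_units(locs)
  if (n < 2) stop("need at least 2 locations")
  d <- as.matrix(stats::dist(unclass(locs)))
  zero <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop(sprintf(
      "coincident points: locations %d and %d are at zero distance; inverse-distance weight undefined",
      zero[1, 2], zero[1, 1]))
  }
  W <- d
  W[row(W) != col(W)] <- d[row(d) != col(d)]^(-alpha)
  diag(W) <- 0
  new_weight_matrix(W, meta = list(kind = "inverse_distance", alpha = alpha),
                    locs = locs)
}

#' Distance-band spatial weights
#'
#' Binary weights selecting pairs whose Euclidean distance lies in the
#' half-open band (d_lo, d_hi]; the building block of spatial correlograms
#' over distance classes.
#'
#' @param locs a `locations` object.
#' @param d_lo,d_hi band limits, `d_hi > d_lo >= 0`.
#' @return a `weight_matrix`; if no pair falls inside the band the matrix
#'   is empty and carries `meta$empty = TRUE` so correlograms can skip the lag.
#' @export
distance_band_weights <- function(locs, d_lo, d_hi) {
  if (!(d_hi > d_lo) || d_lo < 0) stop("need d_hi > d_lo >= 0")
  n <- n_units(locs)
  d <- as.matrix(stats::dist(unclass(locs)))
  sel <- d > d_lo & d <= d_hi
  diag(sel) <- FALSE
  W <- sparseMatrix(i = row(sel)[sel], j = col(sel)[sel], x = 1, dims = c(n, n))
  new_weight_matrix(W,
    meta = list(kind = "distance_band", d_lo = d_lo, d_hi = d_hi,
                empty = !any(sel)),
    locs = locs)
}

#' Write a weight matrix as an edge list
#'
#' Three-column (i, j, w) tab-delimited edge list in deterministic
#' row-major order, preceded by a single `#`-prefixed JSON header recording
#' the construction parameters.
#'
#' @param W a `weight_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(W, path) {
  M <- methods::as(Matrix::t(W$W), "TsparseMatrix")  # transpose -> row-major order
  ord <- order(M@j, M@i)
  df <- data.frame(i = M@j[ord] + 1L, j = M@i[ord] + 1L, w = M@x[ord])
  header <- jsonlite::toJSON(c(W$meta, list(n_units = nrow(W$W))),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("i\tj\tw", con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a weight matrix edge list written by [write_weights()]
#' @param path file path.
#' @return a `weight_matrix` (without locations).
#' @export
read_weights <- function(path) {
  lines <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", lines[1]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  n <- meta$n_units
  W <- sparseMatrix(i = df$i, j = df$j, x = df$w, dims = c(n, n))
  meta$n_units <- NULL
  new_weight_matrix(W, meta = meta)
}
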