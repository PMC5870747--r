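#' Coarse-grain an image stack into a ROI grid
#'
#' Averages each frame over square roi_edge_px x roi_edge_px regions of
#' interest arranged as a grid over the image, the standard reduction of a
#' bioluminescence movie to per-ROI time series. ROIs whose temporal-mean
#' intensity falls below `threshold` (no-tissue regions) are removed from
#' the index space entirely so downstream statistics count only tissue
#' ROIs. Non-divisible image dimensions are cropped per `crop`
#' (`"trailing"`: drop trailing pixel rows/columns).
#'
#' @param frames T x H x W numeric array (or a list of H x W matrices).
#' @param roi_edge_px ROI edge length in pixels (>= 1).
#' @param times optional time grid (hours); default `0:(T-1)`.
#' @param threshold mask ROIs with temporal-mean intensity strictly below
#'   this value; default keeps everything.
#' @param crop crop policy for non-divisible dimensions.
#' @return list with `stack` (a `ts_stack` over the kept ROIs; locations
#'   are ROI centers in pixel coordinates, 0-based) and `mask` (logical
#'   grid-rows x grid-cols matrix, TRUE = kept).
#' @export
coarse_grain_stack <- function(frames, roi_edge_px, times = NULL,
                               threshold = -Inf, crop = c("trailing")) {
  crop <- match.arg(crop)
  if (is.list(frames)) {
    frames <- simplify2array(frames)          # H x W x T
    frames <- aperm(frames, c(3, 1, 2))       # T x H x W
  }
  stopifnot(length(dim(frames)) == 3, roi_edge_px >= 1)
  Tn <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  if (H < roi_edge_px || W < roi_edge_px) stop("image smaller than one ROI")
  gr <- H %/% roi_edge_px; gc <- W %/% roi_edge_px
  frames <- frames[, seq_len(gr * roi_edge_px), seq_len(gc * roi_edge_px),
                   drop = FALSE]
  # block means: row-major ROI order matching grid_locations
  rblock <- rep(seq_len(gr), each = roi_edge_px)
  cblock <- rep(seq_len(gc), each = roi_edge_px)
  vals <- matrix(0, Tn, gr * gc)
  for (t in seq_len(Tn)) {
    m <- rowsum(frames[t, , ], rblock)             # gr x (gc*edge)
    m <- t(rowsum(t(m), cblock))                   # gr x gc sums
    vals[t, ] <- as.vector(t(m)) / roi_edge_px^2   # row-major
  }
  keep <- colMeans(vals) >= threshold
  if (!any(keep)) stop("no usable units: intensity threshold masks all ROIs")
  centers <- grid_locations(gr, gc)
  centers <- unclass(centers) * roi_edge_px + (roi_edge_px - 1) / 2
  locs <- locations(centers[keep, , drop = FALSE], frame = "free")
  times <- times %||% (seq_len(Tn) - 1)
  list(stack = ts_stack(times, vals[, keep, drop = FALSE], locs, "intensity"),
       mask = matrix(keep, gr, gc, byrow = TRUE))
}

#' Read a multi-page TIFF as a T x H x W array
#'
#' @param path TIFF file path.
#' @return numeric array, frames along the first dimension.
#' @export
read_tiff_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF stacks requires the 'tiff' package")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  aperm(arr, c(3, 1, 2))
}

fmt_num <- function(x) format(x, digits = 12, trim = TRUE, scientific = TRUE)

#' Write / read spatial and phase fields as delimited tables
#'
#' Tab-delimited table with columns (id, x, y, value); phase tables are
#' identical with value in radians. A JSON sidecar (`<path>.json`) records
#' the variant, the location frame and the wrapping convention. Phase
#' values outside (-pi, pi] are wrapped on read with a warning.
#'
#' @param field a `spatial_field` or `phase_field`.
#' @param path table file path.
#' @return `path` invisibly (write); the field object (read).
#' @export
write_field_table <- function(field, path) {
  variant <- if (inherits(field, "phase_field")) "circular" else "scalar"
  xy <- unclass(field$locs)
  df <- data.frame(id = seq_along(field$values),
                   x = fmt_num(xy[, "x"]), y = fmt_num(xy[, "y"]),
                   value = fmt_num(field$values))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(variant = variant, frame = attr(field$locs, "frame"),
                            wrapping = "(-pi, pi]", label = field$label),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field_table
#' @param variant `"auto"` reads the sidecar; otherwise `"scalar"` or
#'   `"circular"`.
#' @export
read_field_table <- function(path, variant = c("auto", "scalar", "circular")) {
  variant <- match.arg(variant)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  for (col in c("id", "x", "y", "value")) {
    if (!col %in% names(df)) {
      stop(sprintf("schema error: missing column '%s' in %s", col, path))
    }
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) {
    stop(sprintf("schema error: non-numeric 'value' at row %d of %s", bad[1], path))
  }
  frame <- "free"; label <- ""
  side <- paste0(path, ".json")
  if (variant == "auto") {
    if (!file.exists(side)) {
      variant <- "scalar"
    } else {
      meta <- jsonlite::fromJSON(side)
      variant <- meta$variant
      frame <- meta$frame %||% "free"
      label <- meta$label %||% ""
    }
  } else if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    frame <- meta$frame %||% "free"
  }
  locs <- locations(cbind(as.numeric(df$x), as.numeric(df$y)), frame = frame)
  v <- as.numeric(df$value)
  if (variant == "circular") {
    if (any(v <= -pi | v > pi)) {
      warning("phase values outside (-pi, pi] wrapped on read")
    }
    phase_field(v, locs, label)
  } else {
    spatial_field(v, locs, label)
  }
}

#' Write / read time-series stacks as delimited tables
#'
#' Tab-delimited table: first column `time` (hours), one column per unit
#' (`u1`, `u2`, ...). A JSON sidecar stores the kind, location frame and
#' coordinates. Round-trips are lossless up to 12 significant digits.
#'
#' @param stack a `ts_stack`.
#' @param path table file path.
#' @return `path` invisibly (write); a `ts_stack` (read).
#' @export
write_stack_table <- function(stack, path) {
  df <- data.frame(time = fmt_num(stack$times))
  for (j in seq_len(ncol(stack$values))) {
    df[[paste0("u", j)]] <- fmt_num(stack$values[, j])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  xy <- unclass(stack$locs)
  jsonlite::write_json(list(kind = stack$kind,
                            frame = attr(stack$locs, "frame"),
                            x = xy[, "x"], y = xy[, "y"]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_table
#' @export
read_stack_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!"time" %in% names(df)) {
    stop(sprintf("schema error: missing column 'time' in %s", path))
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    stop(sprintf("schema error: missing location sidecar %s", side))
  }
  meta <- jsonlite::fromJSON(side)
  vals <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  locs <- locations(cbind(meta$x, meta$y), frame = meta$frame %||% "free")
  ts_stack(as.numeric(df$time), vals, locs, meta$kind)
}
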