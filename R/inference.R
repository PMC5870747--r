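#' Monte-Carlo null distribution of Moran's I / circular I
#'
#' Builds the sampling distribution of the Moran statistic under the null
#' hypothesis of no spatial autocorrelation, by either of the two classical
#' constructions: `"resample"` draws the unit values i.i.d. from a stated
#' distribution (fair binary for scalar fields, uniform on the circle for
#' phase fields, unless a custom `sampler` is supplied); `"randomize"`
#' shuffles the observed values over locations, conditioning on the
#' observed value multiset. Degenerate draws (constant fields, or phase
#' draws whose circular mean is undefined) are rejected and redrawn, up to
#' 100 * n_samples attempts; this slightly conditions the null on
#' non-degeneracy.
#'
#' @param field a `spatial_field` or `phase_field`.
#' @param W a `weight_matrix` over the same units.
#' @param mode `"randomize"` (default) or `"resample"`.
#' @param n_samples number of Monte-Carlo draws (>= 100).
#' @param seed integer seed; identical seed + parameters give bit-identical
#'   sample vectors.
#' @param sampler optional `function(n)` returning n values, used in
#'   resample mode.
#' @return a `null_distribution` with fields `samples`, `mode`,
#'   `n_samples`, `seed`, `variant`.
#' @examples
#' f <- binary_grid(10, 10, "random", seed = 7)
#' W <- grid_von_neumann_weights(10, 10, 1)
#' nd <- null_distribution(f, W, "randomize", 999, seed = 1)
#' mean(nd$samples)  # near -1/99
#' @export
null_distribution <- function(field, W, mode = c("randomize", "resample"),
                              n_samples = 999, seed = 1, sampler = NULL) {
  mode <- match.arg(mode)
  if (n_samples < 100) stop("n_samples must be >= 100")
  circular <- inherits(field, "phase_field")
  S0 <- check_field_weights(field, W)
  n <- length(field$values)
  if (mode == "resample" && is.null(sampler)) {
    sampler <- if (circular) {
      function(m) stats::runif(m, -pi, pi)
    } else {
      function(m) sample(c(0, 1), m, replace = TRUE)
    }
  }
  set.seed(seed)
  samples <- if (mode == "randomize") {
    .null_randomize(field$values, W$W, S0, n_samples, circular)
  } else {
    .null_resample(n, W$W, S0, n_samples, sampler, circular)
  }
  structure(list(samples = samples, mode = mode, n_samples = n_samples,
                 seed = seed, variant = if (circular) "circular" else "scalar"),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution: %d %s samples, mode = %s, seed = %d; mean = %.4f, sd = %.4f>\n",
              x$n_samples, x$variant, x$mode, x$seed,
              mean(x$samples), stats::sd(x$samples)))
  invisible(x)
}

# Both the Moran ratio's denominator terms (value multiset, hence mean /
# circular mean and sum of squared deviations) are permutation invariant,
# so randomization reduces to permuting the fixed deviation vector.
.null_randomize <- function(values, Wm, S0, n_samples, circular,
                            chunk = 2000L) {
  n <- length(values)
  if (circular) {
    mu <- circular_mean(values)
    d <- circular_distance(values, mu)
  } else {
    d <- values - mean(values)
  }
  ss <- sum(d^2)
  if (ss <= 0) stop("degenerate field: zero variance under randomization null")
  out <- numeric(n_samples)
  done <- 0L
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    D <- vapply(seq_len(m), function(k) d[sample.int(n)], numeric(n))
    out[done + seq_len(m)] <-
      (n / (S0 * ss)) * Matrix::colSums(D * (Wm %*% D))
    done <- done + m
  }
  out
}

.null_resample <- function(n, Wm, S0, n_samples, sampler, circular,
                           chunk = 2000L) {
  out <- numeric(n_samples)
  done <- 0L
  attempts <- 0L
  cap <- 100L * n_samples
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    V <- matrix(sampler(n * m), nrow = n, ncol = m)
    attempts <- attempts + m
    if (circular) {
      V <- wrap_phase(V)
      Cb <- Matrix::colSums(cos(V)) / n
      Sb <- Matrix::colSums(sin(V)) / n
      ok_mean <- sqrt(Cb^2 + Sb^2) > 1e-9
      mu <- atan2(Sb, Cb)
      D <- wrap_phase(sweep(V, 2, mu, "-"))
    } else {
      D <- sweep(V, 2, Matrix::colSums(V) / n, "-")
      ok_mean <- rep(TRUE, m)
    }
    ss <- Matrix::colSums(D^2)
    ok <- ok_mean & ss > 0
    if (!any(ok)) {
      if (attempts >= cap) stop("too many degenerate resampled fields; check the sampler")
      next
    }
    D <- D[, ok, drop = FALSE]
    stat <- (n / (S0 * ss[ok])) * Matrix::colSums(D * (Wm %*% D))
    take <- min(length(stat), n_samples - done)
    out[done + seq_len(take)] <- stat[seq_len(take)]
    done <- done + take
    if (attempts >= cap && done < n_samples) {
      stop("too many degenerate resampled fields; check the sampler")
    }
  }
  out
}

#' Monte-Carlo p-value
#'
#' Add-one (pseudo-count) Monte-Carlo p-value: the observed statistic is
#' counted among the null samples, so p >= 1/(n_samples + 1) and p = 0 is
#' impossible from a finite sample. The two-sided p doubles the smaller
#' tail, capped at 1.
#'
#' @param observed observed statistic (or a `moran_result`).
#' @param null a `null_distribution`.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return a p-value in (0, 1].
#' @export
p_value <- function(observed, null,
                    alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (inherits(observed, "moran_result")) observed <- observed$statistic
  s <- null$samples
  if (length(s) == 0) stop("empty null distribution")
  m <- length(s)
  p_hi <- (1 + sum(s >= observed)) / (m + 1)
  p_lo <- (1 + sum(s <= observed)) / (m + 1)
  switch(alternative,
         greater = p_hi,
         less = p_lo,
         two_sided = min(1, 2 * min(p_hi, p_lo)))
}

#' Critical band of a Monte-Carlo null
#'
#' Empirical quantile band outside which the null of no spatial
#' autocorrelation is rejected. The two-sided band at level alpha is the
#' (alpha/2, 1 - alpha/2) quantile pair of the null samples (linear
#' interpolation between order statistics); one-sided uses (alpha, 1 - alpha).
#'
#' @param null a `null_distribution`.
#' @param alpha significance level in (0, 1).
#' @param two_sided logical.
#' @return named numeric `c(lower, upper)`.
#' @export
critical_band <- function(null, alpha = 0.05, two_sided = TRUE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  probs <- if (two_sided) c(alpha / 2, 1 - alpha / 2) else c(alpha, 1 - alpha)
  q <- stats::quantile(null$samples, probs, names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Write / read null samples
#'
#' Single-column delimited file with a `#`-prefixed JSON header recording
#' mode, seed, sample count and the two-sided 0.05 critical band.
#'
#' @param null a `null_distribution`.
#' @param path file path.
#' @return `path` invisibly (write); a `null_distribution` (read).
#' @export
write_null <- function(null, path) {
  band <- critical_band(null, 0.05, TRUE)
  header <- jsonlite::toJSON(
    list(mode = null$mode, seed = null$seed, n_samples = null$n_samples,
         variant = null$variant, alpha = 0.05,
         band = unname(band)),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("statistic", con)
  writeLines(format(null$samples, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", readLines(path, n = 1)))
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  structure(list(samples = df$statistic, mode = meta$mode,
                 n_samples = meta$n_samples, seed = meta$seed,
                 variant = meta$variant),
            class = "null_distribution")
}
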