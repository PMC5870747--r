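# shared helpers for building small test instances

rand_free_locs <- function(n, seed) {
  set.seed(seed)
  locations(matrix(runif(2 * n, 0, 10), ncol = 2), frame = "free")
}

rand_scalar_field <- function(n, seed) {
  set.seed(seed)
  spatial_field(rnorm(n), rand_free_locs(n, seed + 1000))
}

rand_phase_field <- function(n, seed) {
  set.seed(seed)
  phase_field(runif(n, -pi, pi), rand_free_locs(n, seed + 1000))
}

# dense matrix view of a weight_matrix, for loop oracles
dense_w <- function(W) as.matrix(W$W)

# brute-force von Neumann adjacency by scanning all cell pairs
brute_von_neumann <- function(rows, cols, r) {
  locs <- unclass(grid_locations(rows, cols))
  n <- nrow(locs)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    md <- abs(locs[i, 1] - locs[j, 1]) + abs(locs[i, 2] - locs[j, 2])
    if (md <= r) W[i, j] <- 1
  }
  W
}
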