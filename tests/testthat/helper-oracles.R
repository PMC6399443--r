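# Independent oracles, written as literal transcriptions of the target
# formulas with no shared code with the package internals.

# Patel's kappa, brute-force transcription.
kappa_oracle <- function(t1, t2, t3, t4) {
  E <- (t1 + t2) * (t1 + t3)
  max_t1 <- min(t1 + t2, t1 + t3)
  min_t1 <- max(0, 2 * t1 + t2 + t3 - 1)
  if (t1 + t2 <= 0 || t1 + t2 >= 1 || t1 + t3 <= 0 || t1 + t3 >= 1) {
    return(NA_real_)
  }
  D <- if (t1 >= E) 1 else 0
  (t1 - E) / (D * (max_t1 - E) + (1 - D) * (E - min_t1))
}

# Random valid contingency tables (counts over n experiments).
random_tables <- function(n_tables, n = 100, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n_tables), function(i) {
    p <- as.numeric(stats::rgamma(4, shape = 1))
    as.numeric(stats::rmultinom(1, n, p / sum(p)))
  }, numeric(4)))
}

# Two-pass textbook Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small mirror-closed grid shared across tests.
tiny_grid <- function(dims = c(10, 10, 10), vox = 2) {
  symmetric_grid(dims, vox)
}

# Random seeded MA-like map with values in [0, 1).
random_unit_map <- function(grid, seed, kind = "MA_probability") {
  set.seed(seed)
  voxel_map(grid, array(stats::runif(prod(grid$dims), 0, 0.9), grid$dims),
            kind = kind)
}

# Wrap bare vectors as 1-D-ish maps for the comparison operations.
vector_map <- function(x, kind = "zscore") {
  g <- volume_grid(c(length(x), 1, 1), 1)
  voxel_map(g, array(x, c(length(x), 1, 1)), kind)
}

world_x_field <- function(grid) {
  xs <- grid_axis_coords(grid, 1)
  array(xs[slice.index(array(0, grid$dims), 1)], grid$dims)
}
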