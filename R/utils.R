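`%||%` <- function(x, y) if (is.null(x)) y else x

# Draw from a normal distribution truncated by rejection-free clipping.
.rnorm_clipped <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# Weighted row-wise sampling: pick one column index per row of a weight
# matrix (non-negative weights, few columns). Used in the movement loop.
.sample_cols <- function(w) {
  nc <- ncol(w)
  cw <- w
  for (j in seq_len(nc - 1L) + 1L) cw[, j] <- cw[, j] + cw[, j - 1L]
  u <- stats::runif(nrow(w)) * cw[, nc]
  1L + rowSums(cw[, -nc, drop = FALSE] < u)
}

# Seed for replicate i derived from a master seed; kept below 2^31.
.replicate_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 16807) %% 2147483647) + 1L
}
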