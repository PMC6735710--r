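# Independent oracles and small fixture builders shared across test files.

# Brute-force DTW: enumerate every monotone warp path from (1,1) to
# (nx,ny) recursively (no memoization) and return the minimal total local
# cost. Exponential, only for tiny instances.
bf_dtw_cost <- function(lc) {
  nx <- nrow(lc); ny <- ncol(lc)
  rec <- function(i, j) {
    if (i == nx && j == ny) return(lc[i, j])
    best <- Inf
    if (i < nx && j < ny) best <- min(best, rec(i + 1L, j + 1L))
    if (i < nx) best <- min(best, rec(i + 1L, j))
    if (j < ny) best <- min(best, rec(i, j + 1L))
    lc[i, j] + best
  }
  rec(1L, 1L)
}

# Brute-force local-cost matrix via the scalar definition.
bf_local_cost_matrix <- function(X, Y) {
  out <- matrix(0, ncol(X), ncol(Y))
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y)))
    out[i, j] <- sum(abs(X[, i] - Y[, j]))
  out
}

# Brute-force symmetric Hausdorff distance: explicit double loops over the
# two point sets (rows = points, cols = x, y).
bf_hausdorff <- function(A, B) {
  h <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      nearest <- Inf
      for (j in seq_len(nrow(Q)))
        nearest <- min(nearest, sqrt(sum((P[i, ] - Q[j, ])^2)))
      worst <- max(worst, nearest)
    }
    worst
  }
  max(h(A, B), h(B, A))
}

# A tiny deterministic profile: p proteins x s slices with distinct values.
toy_matrix <- function(p = 3L, s = 5L, shift = 0) {
  m <- outer(seq_len(p), seq_len(s), function(i, j) i * 10 + j + shift)
  rownames(m) <- sprintf("P%d", seq_len(p))
  colnames(m) <- sprintf("slice_%d", seq_len(s))
  m * 1.0
}

toy_profile <- function(id = "s1", p = 3L, s = 5L, shift = 0)
  new_profile(id, toy_matrix(p, s, shift))

# Write a profile matrix as a CSV fixture file; returns the path.
write_profile_csv <- function(m, path, id_col = "protein_id") {
  df <- data.frame(x = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Hand-built distance table (bypassing the pipeline) for effect-size tests.
fake_dist_table <- function(values, samples) {
  pairs <- utils::combn(samples, 2L)
  stopifnot(ncol(values) == ncol(pairs))
  colnames(values) <- paste(pairs[1, ], pairs[2, ], sep = "|")
  structure(values, pairs = data.frame(a = pairs[1, ], b = pairs[2, ]),
            w = 1, class = c("cx_dist_table", "matrix"))
}
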