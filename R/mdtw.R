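#' Local cost between two gel slices
#'
#' The multi-dimensional local cost pools every protein's signal: it is the
#' sum over proteins of the absolute intensity difference at the two slices.
#' Proteins with high intensities therefore dominate the alignment.
#'
#' @param x,y Numeric intensity vectors over the same protein roster.
#' @return Non-negative scalar; 0 iff the vectors are equal.
#' @export
local_cost <- function(x, y) {
  if (length(x) != length(y))
    stop("protein roster mismatch: ", length(x), " vs ", length(y))
  sum(abs(x - y))
}

# nx-by-ny matrix of local costs between all slice pairs of two
# protein-by-slice matrices over the same roster.
local_cost_matrix <- function(X, Y) {
  if (nrow(X) != nrow(Y)) stop("protein roster mismatch")
  nx <- ncol(X)
  out <- matrix(0, nx, ncol(Y))
  for (i in seq_len(nx)) out[i, ] <- colSums(abs(Y - X[, i]))
  out
}

# Dynamic-programming core: accumulate the classic three-move recursion over
# a local-cost matrix and trace back the optimal warp path.
# Ties among predecessors are broken deterministically: diagonal, then the
# predecessor along the first argument's axis (x-1, y), then (x, y-1).
dtw_core <- function(lc) {
  nx <- nrow(lc); ny <- ncol(lc)
  if (nx < 2L || ny < 2L) stop("sequences must have length >= 2")
  acc <- matrix(Inf, nx, ny)
  acc[1, 1] <- lc[1, 1]
  acc[, 1] <- cumsum(lc[, 1])
  acc[1, ] <- cumsum(lc[1, ])
  for (i in 2:nx) for (j in 2:ny)
    acc[i, j] <- lc[i, j] + min(acc[i - 1, j - 1], acc[i - 1, j],
                                acc[i, j - 1])
  # traceback
  i <- nx; j <- ny
  path <- matrix(0L, nx + ny, 2L)
  k <- 1L
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) { j <- j - 1L
    } else if (j == 1L) { i <- i - 1L
    } else {
      pred <- c(acc[i - 1, j - 1], acc[i - 1, j], acc[i, j - 1])
      mv <- which.min(pred)  # first minimum: diagonal > (x-1,y) > (x,y-1)
      if (mv == 1L) { i <- i - 1L; j <- j - 1L }
      else if (mv == 2L) i <- i - 1L
      else j <- j - 1L
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  steps <- path[k:1, , drop = FALSE]
  colnames(steps) <- c("x", "y")
  list(steps = steps, cost = acc[nx, ny], accumulated = acc)
}

finish_pairwise <- function(core, keep_matrices, lc) {
  steps <- core$steps
  L <- nrow(steps)
  gx <- which(c(FALSE, diff(steps[, 1]) == 0L))  # x index repeats: gap in x
  gy <- which(c(FALSE, diff(steps[, 2]) == 0L))
  structure(list(steps = steps, cost = core$cost, length = L,
                 gaps_x = gx, gaps_y = gy,
                 local = if (keep_matrices) lc else NULL,
                 accumulated = if (keep_matrices) core$accumulated else NULL),
            class = "cx_pairwise")
}

#' Pairwise multi-dimensional dynamic time warping
#'
#' Aligns two profiles over a shared protein roster with the unconstrained
#' three-move DTW recursion (no warping window, no step weights, both
#' endpoints matched). The global cost is the sum of local costs along the
#' optimal warp path and carries no gap penalty, so it measures profile
#' difference independently of gel-to-gel migration shifts.
#'
#' @param x,y Protein-by-slice matrices (same rownames/roster) or
#'   `cx_profile` objects.
#' @param keep_matrices Keep the local and accumulated cost matrices in the
#'   result (debugging aid).
#' @return A `cx_pairwise`: `steps` (warp path, 1-based index pairs), `cost`
#'   (global cost), `length` (aligned length), `gaps_x`/`gaps_y` (aligned
#'   positions where that side's slice index repeats, i.e. inserted slices).
#' @export
dtw_align <- function(x, y, keep_matrices = FALSE) {
  X <- if (inherits(x, "cx_profile")) x$intensities else x
  Y <- if (inherits(y, "cx_profile")) y$intensities else y
  if (ncol(X) < 2L || ncol(Y) < 2L) stop("sequences must have length >= 2")
  lc <- local_cost_matrix(X, Y)
  finish_pairwise(dtw_core(lc), keep_matrices, lc)
}

#' Align two alignments (alignment-of-alignments DTW)
#'
#' Identical recursion to [dtw_align()] but the local cost at an aligned
#' position pair is the average local cost over all cross sample pairs
#' between the two alignments; gap-extended (already warped) positions
#' contribute their repeated values. Reduces exactly to [dtw_align()] when
#' both sides hold a single sample.
#'
#' @param A,B Lists of protein-by-slice matrices (one per member sample, all
#'   equal width within a side), or `cx_alignment` objects.
#' @param keep_matrices As in [dtw_align()].
#' @return A `cx_pairwise`.
#' @export
dtw_align_alignments <- function(A, B, keep_matrices = FALSE) {
  MA <- if (inherits(A, "cx_alignment")) warped_matrices(A) else A
  MB <- if (inherits(B, "cx_alignment")) warped_matrices(B) else B
  if (!is.list(MA)) MA <- list(MA)
  if (!is.list(MB)) MB <- list(MB)
  lc <- 0
  for (X in MA) for (Y in MB) lc <- lc + local_cost_matrix(X, Y)
  lc <- lc / (length(MA) * length(MB))
  finish_pairwise(dtw_core(lc), keep_matrices, lc)
}

#' @export
print.cx_pairwise <- function(x, ...) {
  cat("pairwise DTW alignment: length ", x$length, ", global cost ",
      format(x$cost), ", gaps x/y: ", length(x$gaps_x), "/",
      length(x$gaps_y), "\n", sep = "")
  invisible(x)
}
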