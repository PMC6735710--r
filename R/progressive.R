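#' Pairwise global-cost matrix of a profile set
#'
#' Runs [dtw_align()] for every sample pair of a (normalized) profile set.
#'
#' @param profile_set A `cx_profile_set` with >= 2 samples.
#' @return Symmetric n-by-n matrix of global costs, zero diagonal, dimnames
#'   the sample ids.
#' @export
pairwise_cost_matrix <- function(profile_set) {
  stopifnot(inherits(profile_set, "cx_profile_set"))
  ps <- profile_set$profiles
  n <- length(ps)
  ids <- names(ps)
  costs <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) stop("need at least 2 samples")
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    c_ij <- dtw_align(ps[[i]], ps[[j]])$cost
    costs[i, j] <- costs[j, i] <- c_ij
  }
  costs
}

#' Build a single-linkage guide tree from a cost matrix
#'
#' Agglomerates samples by single linkage on the pairwise global costs; the
#' merge order determines the progressive alignment order. Ties are broken
#' deterministically by the smallest original member index of the candidate
#' pair (then the other side's smallest index).
#'
#' @param costs Symmetric non-negative matrix with sample-id dimnames.
#' @return A `cx_guide_tree`: `merge` (hclust-style, negative = leaf),
#'   `height` (linkage cost per merge, non-decreasing), `labels`,
#'   `members` (leaf index sets per internal node).
#' @export
build_guide_tree <- function(costs) {
  if (any(is.na(costs))) stop("NA/NaN in cost matrix")
  if (!isSymmetric(unname(costs))) stop("cost matrix must be symmetric")
  n <- nrow(costs)
  if (n < 2L) stop("need at least 2 samples")
  labels <- rownames(costs)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))

  # active clusters: node code (negative leaf / positive merge id) + members
  node <- -seq_len(n)
  members <- as.list(seq_len(n))
  D <- costs
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members_out <- vector("list", n - 1L)
  active <- rep(TRUE, n)

  for (m in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_key <- NULL
    for (a in idx) for (b in idx[idx > a]) {
      key <- c(D[a, b], sort(c(min(members[[a]]), min(members[[b]]))))
      if (is.null(best) ||
          key[1] < best_key[1] ||
          (key[1] == best_key[1] &&
           (key[2] < best_key[2] ||
            (key[2] == best_key[2] && key[3] < best_key[3])))) {
        best <- c(a, b); best_key <- key
      }
    }
    a <- best[1]; b <- best[2]
    merge[m, ] <- c(node[a], node[b])
    height[m] <- D[a, b]
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    members_out[[m]] <- members[[a]]
    node[a] <- m
    active[b] <- FALSE
    # single linkage update
    for (k in which(active)) if (k != a)
      D[a, k] <- D[k, a] <- min(D[a, k], D[b, k])
    D[b, ] <- D[, b] <- Inf
  }
  structure(list(merge = merge, height = height, labels = labels,
                 members = members_out), class = "cx_guide_tree")
}

#' Serialize a guide tree to Newick
#' @param tree A `cx_guide_tree`.
#' @return A single Newick string with linkage costs as branch annotations.
#' @export
as_newick <- function(tree) {
  render <- function(code) {
    if (code < 0L) return(tree$labels[-code])
    h <- format(tree$height[code])
    paste0("(", render(tree$merge[code, 1]), ",",
           render(tree$merge[code, 2]), "):", h)
  }
  paste0(render(nrow(tree$merge)), ";")
}

#' @export
print.cx_guide_tree <- function(x, ...) {
  cat("guide tree over", length(x$labels), "samples:\n ", as_newick(x), "\n")
  invisible(x)
}

#' Progressive multiple alignment of a profile set
#'
#' Aligns all samples into one multiple alignment: leaves start as trivial
#' alignments, then merges follow the guide tree bottom-up, each merge
#' aligning two alignments with [dtw_align_alignments()] and propagating the
#' resulting gaps to every member of each side. A gap (inserted slice) in a
#' sample is realized by repeating the preceding slice's intensities, so
#' removing a sample's inserted positions recovers its input matrix exactly.
#' At each merge the side containing the lowest original sample index is the
#' first DTW argument (determinism).
#'
#' @param profile_set A (normalized) `cx_profile_set`.
#' @param tree Optional `cx_guide_tree`; computed from
#'   [pairwise_cost_matrix()] when missing.
#' @param costs Optional precomputed cost matrix (used when `tree` missing,
#'   and stored as provenance).
#' @return A `cx_alignment`: `sample_ids`, `protein_ids`, `mats` (the input
#'   matrices), `idx` (per sample, the non-decreasing map from aligned
#'   positions to original slice indices; repeats mark insertions), `L`
#'   (aligned length), `cost_matrix`, `tree`.
#' @export
progressive_align <- function(profile_set, tree = NULL, costs = NULL) {
  stopifnot(inherits(profile_set, "cx_profile_set"))
  ps <- profile_set$profiles
  ids <- names(ps)
  if (is.null(costs) && is.null(tree)) costs <- pairwise_cost_matrix(profile_set)
  if (is.null(tree)) tree <- build_guide_tree(costs)
  if (!setequal(tree$labels, ids))
    stop("guide tree leaves do not match sample ids")
  ord <- match(tree$labels, ids)  # leaf i in tree = sample ord[i]

  # working alignment per node: members (leaf indices in tree numbering),
  # idx list keyed by sample id
  leaf_aln <- function(i) {
    s <- ps[[ord[i]]]
    list(members = i,
         idx = stats::setNames(list(seq_len(ncol(s$intensities))),
                               s$sample_id))
  }
  nodes <- list()
  get_node <- function(code) if (code < 0L) leaf_aln(-code) else nodes[[code]]
  mats <- lapply(ps, `[[`, "intensities")

  warped_of <- function(aln)
    lapply(names(aln$idx), function(s) mats[[s]][, aln$idx[[s]], drop = FALSE])

  for (m in seq_len(nrow(tree$merge))) {
    A <- get_node(tree$merge[m, 1])
    B <- get_node(tree$merge[m, 2])
    if (min(B$members) < min(A$members)) { tmp <- A; A <- B; B <- tmp }
    pw <- dtw_align_alignments(warped_of(A), warped_of(B))
    idx <- c(lapply(A$idx, function(v) v[pw$steps[, 1]]),
             lapply(B$idx, function(v) v[pw$steps[, 2]]))
    nodes[[m]] <- list(members = sort(c(A$members, B$members)), idx = idx)
  }
  final <- nodes[[nrow(tree$merge)]]
  idx <- final$idx[ids]  # original input order
  L <- length(idx[[1]])
  structure(list(sample_ids = ids,
                 protein_ids = profile_set$protein_ids,
                 mats = mats, idx = idx, L = L,
                 cost_matrix = costs, tree = tree),
            class = "cx_alignment")
}

#' Warped matrix of one sample on the common aligned axis
#' @param alignment A `cx_alignment`.
#' @param sample Sample id.
#' @return Protein-by-L matrix with columns `pos_1..pos_L`.
#' @export
warped_matrix <- function(alignment, sample) {
  m <- alignment$mats[[sample]][, alignment$idx[[sample]], drop = FALSE]
  colnames(m) <- paste0("pos_", seq_len(ncol(m)))
  m
}

#' All warped matrices of an alignment
#' @param alignment A `cx_alignment`.
#' @return Named list of warped matrices.
#' @export
warped_matrices <- function(alignment) {
  stats::setNames(lapply(alignment$sample_ids,
                         function(s) warped_matrix(alignment, s)),
                  alignment$sample_ids)
}

#' Remove a sample's inserted positions from its warped matrix
#'
#' De-warp identity: the result equals the sample's (normalized) input matrix
#' bit-exactly.
#' @param alignment A `cx_alignment`.
#' @param sample Sample id.
#' @return The recovered original matrix.
#' @export
dewarp_matrix <- function(alignment, sample) {
  idx <- alignment$idx[[sample]]
  keep <- c(TRUE, diff(idx) != 0L)
  m <- alignment$mats[[sample]][, idx[keep], drop = FALSE]
  colnames(m) <- colnames(alignment$mats[[sample]])
  m
}

#' Table of inserted-slice positions per sample
#'
#' @param alignment A `cx_alignment`.
#' @return data.frame with columns `sample` and `position` (1-based aligned
#'   axis), one row per insertion; zero rows when the alignment has no gaps.
#' @export
insertion_report <- function(alignment) {
  rows <- lapply(alignment$sample_ids, function(s) {
    idx <- alignment$idx[[s]]
    pos <- which(c(FALSE, diff(idx) == 0L))
    if (length(pos)) data.frame(sample = s, position = pos) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(sample = character(0),
                                      position = integer(0))
  out
}

#' @export
print.cx_alignment <- function(x, ...) {
  cat("multiple alignment: ", length(x$sample_ids), " samples, ",
      length(x$protein_ids), " proteins, aligned length ", x$L, ", ",
      nrow(insertion_report(x)), " insertions\n", sep = "")
  invisible(x)
}
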