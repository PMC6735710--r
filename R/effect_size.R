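#' Hausdorff effect size (HES) per protein
#'
#' For each protein, HES is the mean Hausdorff distance over the B
#' between-group sample pairs divided by the mean over the W within-group
#' pairs. Large values flag proteins whose migration differs consistently
#' between cases and controls while staying consistent within each group.
#' Degenerate cases are flagged explicitly rather than propagating NaN:
#' mean_within = 0 with mean_between > 0 gives `Inf` (ranked top, flag
#' `"infinite"`); both means 0 gives `NA` (ranked bottom, flag
#' `"undefined"`). Ties in HES are broken by protein id.
#'
#' @param distances A `cx_dist_table` from [distance_table()].
#' @param groups A `cx_groups`; every id must be a sample of the table and at
#'   least one group must have >= 2 members (otherwise W = 0).
#' @return A `cx_hes_table` data.frame sorted by rank with columns
#'   `protein_id`, `hes`, `mean_between`, `mean_within`, `n_between`,
#'   `n_within`, `flag`, `rank`.
#' @export
hes <- function(distances, groups) {
  stopifnot(inherits(distances, "cx_dist_table"), inherits(groups, "cx_groups"))
  pairs <- attr(distances, "pairs")
  samples <- unique(c(pairs$a, pairs$b))
  missing <- setdiff(c(groups$case, groups$control), samples)
  if (length(missing))
    stop("group sample(s) not in distance table: ",
         paste(missing, collapse = ", "))
  if (length(groups$case) == 0L || length(groups$control) == 0L)
    stop("both groups must be non-empty")
  grp_of <- function(s) ifelse(s %in% groups$case, "case",
                               ifelse(s %in% groups$control, "control", NA))
  ga <- grp_of(pairs$a); gb <- grp_of(pairs$b)
  use <- !is.na(ga) & !is.na(gb)
  between <- use & ga != gb
  within <- use & ga == gb
  B <- sum(between); W <- sum(within)
  if (W == 0L)
    stop("W = 0: at least one group needs >= 2 samples to measure ",
         "within-group variation")
  mb <- rowMeans(distances[, between, drop = FALSE])
  mw <- rowMeans(distances[, within, drop = FALSE])
  h <- ifelse(mw > 0, mb / mw, ifelse(mb > 0, Inf, NA_real_))
  flag <- ifelse(is.na(h), "undefined",
                 ifelse(is.infinite(h), "infinite", "ok"))
  tab <- data.frame(protein_id = rownames(distances), hes = h,
                    mean_between = mb, mean_within = mw,
                    n_between = B, n_within = W, flag = flag,
                    row.names = NULL)
  defined <- !is.na(tab$hes)
  ord <- c(which(defined)[order(-tab$hes[defined],
                                tab$protein_id[defined])],
           which(!defined)[order(tab$protein_id[!defined])])
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("cx_hes_table", "data.frame")
  tab
}

#' Export the HES ranking as a .rnk file for preranked GSEA
#'
#' Two tab-separated columns (id, score), no header, descending score.
#' Infinite HES values are replaced by 10 times the largest finite HES (GSEA
#' needs finite scores) with a warning; undefined proteins are omitted from
#' the .rnk and listed in a sidecar `<path>.excluded.txt`.
#'
#' @param table A `cx_hes_table`.
#' @param path Output .rnk path.
#' @return Invisibly, `path`.
#' @export
export_ranked <- function(table, path) {
  stopifnot(inherits(table, "cx_hes_table"))
  keep <- table$flag != "undefined"
  excluded <- table$protein_id[!keep]
  tab <- table[keep, , drop = FALSE]
  score <- tab$hes
  if (any(is.infinite(score))) {
    finite_max <- suppressWarnings(max(score[is.finite(score)]))
    cap <- if (is.finite(finite_max) && finite_max > 0) finite_max * 10 else 10
    warning(sum(is.infinite(score)), " infinite HES value(s) written as ",
            format(cap))
    score[is.infinite(score)] <- cap
  }
  writeLines(paste(tab$protein_id, sprintf("%.10g", score), sep = "\t"),
             path)
  if (length(excluded))
    writeLines(excluded, paste0(path, ".excluded.txt"))
  invisible(path)
}

#' Per-complex rank summary (leading-edge convenience report)
#'
#' For each gene set (protein complex), reports where its members fall in the
#' HES ranking and how many land in the top `top_k`. This is a quick-look
#' companion to running full preranked GSEA externally on the exported .rnk
#' and GMT files; it computes no enrichment statistics.
#'
#' @param table A `cx_hes_table`.
#' @param sets A `cx_gene_sets`.
#' @param top_k Rank cutoff (default 50; must be <= number of proteins).
#' @return data.frame with columns `set`, `n_members`, `n_matched`,
#'   `n_in_top_k`, `member_ranks` (1-based, sorted, comma-separated).
#' @export
leading_edge_summary <- function(table, sets, top_k = 50L) {
  stopifnot(inherits(table, "cx_hes_table"))
  if (top_k > nrow(table))
    stop("top_k (", top_k, ") exceeds number of proteins (", nrow(table), ")")
  rows <- lapply(names(sets), function(nm) {
    ranks <- sort(table$rank[table$protein_id %in% sets[[nm]]])
    data.frame(set = nm, n_members = length(sets[[nm]]),
               n_matched = length(ranks),
               n_in_top_k = sum(ranks <= top_k),
               member_ranks = paste(ranks, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
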