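#' Read a complexome profile from a tabular file
#'
#' A complexome profile is one sample's protein-by-slice intensity matrix:
#' rows are proteins (identified by `id_column`), columns are gel slices in
#' file order (taken as the low-to-high apparent-mass direction), cells are
#' non-negative iBAQ-style intensities. Empty cells are read as 0; explicit
#' `NaN` cells are set to 0 with a warning reporting how many were replaced.
#'
#' @param path Path to a CSV, TSV or xlsx file with a header row.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"xlsx"`. `"auto"` guesses
#'   from the file extension (xlsx needs the readxl package).
#' @param id_column Name of the protein-identifier column. Default: the first
#'   column.
#' @param annotation_columns Character vector of non-intensity columns to
#'   carry along as annotation (e.g. gene symbol, description). Every column
#'   that is neither the id nor an annotation is treated as a slice column and
#'   must be numeric.
#' @param slice_columns `"auto"` (all remaining columns, in file order) or an
#'   explicit character vector of slice column names.
#' @param collapse_by Optional annotation column holding a gene key. When
#'   given, rows sharing a key are collapsed to the single row with the
#'   highest total intensity and the key becomes the protein id (the usual
#'   rule for gene-level complexome tables).
#' @param sample_id Sample identifier; default: file name without extension.
#' @return A `cx_profile` object: list with `sample_id`, `protein_ids`,
#'   `intensities` (matrix, rownames = protein ids) and `annotations`.
#' @export
read_profile <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                         id_column = NULL, annotation_columns = character(),
                         slice_columns = "auto", collapse_by = NULL,
                         sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("profile file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx", xls = "xlsx", "csv")
  }
  df <- switch(format,
    csv  = data.table::fread(path, sep = ",", header = TRUE,
                             data.table = FALSE, keepLeadingZeros = TRUE),
    tsv  = data.table::fread(path, sep = "\t", header = TRUE,
                             data.table = FALSE, keepLeadingZeros = TRUE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package")
      as.data.frame(readxl::read_excel(path))
    })
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path)
  if (length(annotation_columns) &&
      !all(annotation_columns %in% names(df)))
    stop("annotation column(s) not found: ",
         paste(setdiff(annotation_columns, names(df)), collapse = ", "))

  if (identical(slice_columns, "auto")) {
    slice_columns <- setdiff(names(df), c(id_column, annotation_columns))
  } else if (!all(slice_columns %in% names(df))) {
    stop("slice column(s) not found: ",
         paste(setdiff(slice_columns, names(df)), collapse = ", "))
  }
  if (length(slice_columns) < 2L)
    stop("a profile needs at least 2 slice columns; got ",
         length(slice_columns))

  ids <- as.character(df[[id_column]])
  mat <- matrix(0, nrow(df), length(slice_columns),
                dimnames = list(NULL, slice_columns))
  n_nan <- 0L
  for (j in seq_along(slice_columns)) {
    col <- df[[slice_columns[j]]]
    if (is.character(col)) {
      blank <- is.na(col) | !nzchar(trimws(col))
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!blank & is.na(num) & !toupper(trimws(col)) %in% "NAN")
      if (length(bad))
        stop("non-numeric value '", col[bad[1]], "' in slice column '",
             slice_columns[j], "', row ", bad[1], " (", ids[bad[1]], ")")
      num[blank] <- 0
      col <- num
    }
    nan <- is.nan(col)
    n_nan <- n_nan + sum(nan)
    col[is.na(col)] <- 0
    neg <- which(col < 0)
    if (length(neg))
      stop("negative intensity ", col[neg[1]], " in slice column '",
           slice_columns[j], "', row ", neg[1], " (", ids[neg[1]], ")")
    mat[, j] <- col
  }
  if (n_nan > 0L)
    warning(n_nan, " NaN cell(s) in ", path, " set to 0")

  ann <- if (length(annotation_columns))
    df[annotation_columns] else NULL

  if (!is.null(collapse_by)) {
    if (!collapse_by %in% names(df))
      stop("collapse_by column '", collapse_by, "' not found")
    key <- as.character(df[[collapse_by]])
    keep <- vapply(split(seq_along(key), key), function(i)
      i[which.max(rowSums(mat[i, , drop = FALSE]))], integer(1))
    keep <- sort(unname(keep))
    mat <- mat[keep, , drop = FALSE]
    ids <- key[keep]
    if (!is.null(ann)) ann <- ann[keep, , drop = FALSE]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(utils::head(dup, 10), collapse = ", "),
         if (length(dup) > 10) " ..." else "")
  rownames(mat) <- ids
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  new_profile(sample_id, mat, annotations = ann)
}

#' Construct a profile object from a matrix
#'
#' @param sample_id Sample identifier.
#' @param intensities Numeric matrix, proteins in rows (rownames = ids),
#'   slices in columns.
#' @param annotations Optional data.frame of per-protein annotation.
#' @return A `cx_profile`.
#' @export
new_profile <- function(sample_id, intensities, annotations = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)))
  p <- structure(list(sample_id = as.character(sample_id),
                      protein_ids = rownames(intensities),
                      intensities = intensities,
                      annotations = annotations),
                 class = "cx_profile")
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  m <- p$intensities
  if (ncol(m) < 2L) stop("profile '", p$sample_id, "' has < 2 slices")
  if (anyDuplicated(p$protein_ids))
    stop("duplicate protein ids in profile '", p$sample_id, "'")
  if (any(!is.finite(m)))
    stop("non-finite intensity in profile '", p$sample_id, "'")
  if (any(m < 0))
    stop("negative intensity in profile '", p$sample_id, "'")
  invisible(p)
}

#' @export
print.cx_profile <- function(x, ...) {
  cat("complexome profile '", x$sample_id, "': ",
      nrow(x$intensities), " proteins x ", ncol(x$intensities),
      " slices\n", sep = "")
  invisible(x)
}

#' Write a profile to a delimited text file
#'
#' Inverse of [read_profile()] for the CSV/TSV dialect; round-trips
#' `protein_ids` and `intensities` up to numeric formatting.
#'
#' @param profile A `cx_profile`.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_profile <- function(profile, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- data.frame(protein_id = profile$protein_ids,
                   profile$intensities, check.names = FALSE,
                   row.names = NULL)
  data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  invisible(path)
}

#' Harmonize profiles onto a shared protein roster
#'
#' Profiles from different runs rarely report identical protein sets. The
#' shared roster is the union of all rosters (first-seen order), or `subset`
#' if given; proteins absent from a sample get an all-zero row there, so that
#' presence/absence differences are visible to the alignment cost. Samples may
#' have different slice counts.
#'
#' @param profiles List of `cx_profile` objects (>= 2, unique sample ids).
#' @param subset Optional character vector restricting the roster (e.g. a
#'   mitochondrial inclusion list). Order of `subset` is kept.
#' @return A `cx_profile_set`: list with `profiles` (named list, harmonized)
#'   and `protein_ids`.
#' @export
build_profile_set <- function(profiles, subset = NULL) {
  if (inherits(profiles, "cx_profile_set")) profiles <- profiles$profiles
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  all_prot <- unique(unlist(lapply(profiles, `[[`, "protein_ids")))
  if (!is.null(subset)) {
    roster <- subset[subset %in% all_prot]
    if (length(roster) == 0L)
      stop("subset shares no proteins with any profile")
  } else roster <- all_prot

  harmonized <- lapply(profiles, function(p) {
    m <- matrix(0, length(roster), ncol(p$intensities),
                dimnames = list(roster, colnames(p$intensities)))
    common <- intersect(roster, p$protein_ids)
    m[common, ] <- p$intensities[common, , drop = FALSE]
    new_profile(p$sample_id, m)
  })
  names(harmonized) <- ids
  structure(list(profiles = harmonized, protein_ids = roster),
            class = "cx_profile_set")
}

#' @export
print.cx_profile_set <- function(x, ...) {
  cat("profile set: ", length(x$profiles), " samples, ",
      length(x$protein_ids), " proteins\n", sep = "")
  invisible(x)
}

#' Read a sample-to-group assignment file
#'
#' Two tab- or comma-separated columns, no header: sample id, group label.
#'
#' @param path Path to the group file.
#' @param case_label,control_label Labels identifying the two groups.
#' @return A `cx_groups` object: list with `case` and `control` id vectors.
#' @export
read_groups <- function(path, case_label = "case", control_label = "control") {
  if (!file.exists(path)) stop("group file not found: ", path)
  df <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(df) < 2L) stop("group file needs two columns (sample, group)")
  sample <- as.character(df[[1]]); grp <- as.character(df[[2]])
  bad <- setdiff(unique(grp), c(case_label, control_label))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected '", case_label, "' / '", control_label, "')")
  if (anyDuplicated(sample))
    stop("sample(s) listed more than once: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  new_groups(sample[grp == case_label], sample[grp == control_label])
}

#' Construct a group assignment
#' @param case,control Character vectors of sample ids (disjoint).
#' @return A `cx_groups`.
#' @export
new_groups <- function(case, control) {
  if (length(intersect(case, control)))
    stop("samples in both groups: ",
         paste(intersect(case, control), collapse = ", "))
  structure(list(case = as.character(case),
                 control = as.character(control)), class = "cx_groups")
}

#' Read gene sets (protein complexes) from GMT or two-column format
#'
#' GMT: one set per line, `name<TAB>description<TAB>member1<TAB>member2...`.
#' Two-column: repeated `set<TAB>member` rows. Members not matching any
#' profile are kept; matching happens downstream.
#'
#' @param path Path to the set file.
#' @param format `"gmt"` or `"two_column"`.
#' @return A `cx_gene_sets`: named list of member id vectors.
#' @export
read_gene_sets <- function(path, format = c("gmt", "two_column")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene set file: ", path)
  if (format == "gmt") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nms <- vapply(parts, `[`, character(1), 1)
    sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  } else {
    df <- data.table::fread(path, header = FALSE, data.table = FALSE)
    if (ncol(df) < 2L) stop("two-column format needs two columns")
    sets <- lapply(split(as.character(df[[2]]), df[[1]]), unique)
    nms <- names(sets)
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("duplicate set name(s): ", paste(dup, collapse = ", "))
  empty <- nms[lengths(sets) == 0L]
  if (length(empty)) stop("empty set(s): ", paste(empty, collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "cx_gene_sets")
}

#' Write an alignment to disk
#'
#' Writes one warped matrix per sample (`aligned_<sample>.csv`, aligned-axis
#' columns `pos_1..pos_L`), the insertion (gap) table `insertions.csv`
#' (long format: sample, 1-based aligned position), the pairwise global-cost
#' matrix `pairwise_costs.csv` and the guide tree `guide_tree.nwk`.
#'
#' @param alignment A `cx_alignment` from [progressive_align()].
#' @param out_dir Output directory (created if missing).
#' @param format Only `"csv"` is supported in this build; `"xlsx"` errors
#'   because no xlsx writer is available.
#' @return Invisibly, the vector of written paths.
#' @export
write_alignment <- function(alignment, out_dir, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx")
    stop("xlsx output is not supported in this build; use format = 'csv'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in alignment$sample_ids) {
    w <- warped_matrix(alignment, s)
    df <- data.frame(protein_id = rownames(w), w, check.names = FALSE,
                     row.names = NULL)
    p <- file.path(out_dir, paste0("aligned_", s, ".csv"))
    data.table::fwrite(df, p)
    paths <- c(paths, p)
  }
  ins <- insertion_report(alignment)
  p <- file.path(out_dir, "insertions.csv")
  data.table::fwrite(ins, p); paths <- c(paths, p)
  if (!is.null(alignment$cost_matrix)) {
    cm <- data.frame(sample = rownames(alignment$cost_matrix),
                     alignment$cost_matrix, check.names = FALSE,
                     row.names = NULL)
    p <- file.path(out_dir, "pairwise_costs.csv")
    data.table::fwrite(cm, p); paths <- c(paths, p)
  }
  if (!is.null(alignment$tree)) {
    p <- file.path(out_dir, "guide_tree.nwk")
    writeLines(as_newick(alignment$tree), p); paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back the warped matrices written by [write_alignment()]
#'
#' @param dir Directory holding `aligned_*.csv` files.
#' @return Named list of warped matrices (equal column counts).
#' @export
read_aligned_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^aligned_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no aligned_*.csv files in ", dir)
  mats <- lapply(files, function(f) {
    df <- data.table::fread(f, data.table = FALSE)
    m <- as.matrix(df[-1]); rownames(m) <- df[[1]]
    m
  })
  names(mats) <- sub("^aligned_(.*)\\.csv$", "\\1", basename(files))
  L <- unique(vapply(mats, ncol, integer(1)))
  if (length(L) != 1L) stop("aligned matrices have differing lengths")
  mats
}
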