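#' Generate one synthetic complexome profile
#'
#' Each protein's migration curve is a sum of Gaussian peaks over the slice
#' axis (slices 1..n_slices), multiplied by lognormal noise with unit mean
#' and coefficient of variation `noise_cv` (mass-spec intensities are
#' positive and right-skewed), with cells zeroed independently with
#' probability `dropout_p` (missed identifications). With `noise_cv = 0` and
#' `dropout_p = 0` the matrix is the exact Gaussian mixture, so the value at
#' an integer peak center equals the peak height.
#'
#' @param sample_id Sample identifier.
#' @param protein_ids Protein roster (character).
#' @param n_slices Number of gel slices (>= 2).
#' @param peaks data.frame with columns `protein_id`, `center` (slice units,
#'   within [1, n_slices]), `width` (Gaussian sigma, slices), `height`.
#'   Multiple rows per protein are summed.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param dropout_p Per-cell zeroing probability in [0, 1).
#' @param seed Optional integer fixing all randomness.
#' @return A `cx_profile`.
#' @export
generate_profile <- function(sample_id, protein_ids, n_slices, peaks,
                             noise_cv = 0.1, dropout_p = 0.02, seed = NULL) {
  stopifnot(n_slices >= 2L, noise_cv >= 0, dropout_p >= 0, dropout_p < 1)
  bad <- setdiff(peaks$protein_id, protein_ids)
  if (length(bad))
    stop("peak(s) for protein(s) not in roster: ",
         paste(unique(bad), collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- seq_len(n_slices)
  mat <- matrix(0, length(protein_ids), n_slices,
                dimnames = list(protein_ids,
                                sprintf("slice_%d", s)))
  for (k in seq_len(nrow(peaks))) {
    pk <- peaks[k, ]
    mat[pk$protein_id, ] <- mat[pk$protein_id, ] +
      pk$height * exp(-0.5 * ((s - pk$center) / pk$width)^2)
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(stats::rlnorm(length(mat), -sdlog^2 / 2, sdlog),
                    nrow(mat))
    mat <- mat * noise
  }
  if (dropout_p > 0)
    mat[matrix(stats::runif(length(mat)) < dropout_p, nrow(mat))] <- 0
  new_profile(sample_id, mat)
}

#' Apply a known gel warp to a profile
#'
#' Emulates gel-to-gel migration shifts: the slices listed in `insert_at`
#' are duplicated in place (lengthening the lane, shifting everything after
#' them by one slice each), and the whole matrix is multiplied by a
#' gel-specific intensity factor. The duplications are exactly what the
#' aligner should undo with inserted gaps in the other samples.
#'
#' @param profile A `cx_profile`.
#' @param insert_at Integer original-slice indices to duplicate (sorted,
#'   within range); empty for no warp.
#' @param factor Positive per-gel intensity factor.
#' @return Warped `cx_profile` with `n_slices + length(insert_at)` columns;
#'   attribute `warp` records `insert_at` and `factor`.
#' @export
apply_warp <- function(profile, insert_at = integer(0), factor = 1) {
  stopifnot(factor > 0)
  n <- ncol(profile$intensities)
  insert_at <- as.integer(insert_at)
  if (length(insert_at) &&
      (any(insert_at < 1L) || any(insert_at > n)))
    stop("insert_at out of range 1..", n)
  take <- sort(c(seq_len(n), insert_at))
  m <- profile$intensities[, take, drop = FALSE] * factor
  colnames(m) <- sprintf("slice_%d", seq_len(ncol(m)))
  out <- new_profile(profile$sample_id, m)
  attr(out, "warp") <- list(insert_at = sort(insert_at), factor = factor)
  out
}

#' Generate a labeled case/control study with known ground truth
#'
#' Emulates a typical complexome-profiling comparison: `n_case + n_control`
#' samples of `n_proteins` proteins over `n_slices` slices, run on `n_gels`
#' gels (round-robin assignment). Every protein gets one Gaussian peak with a
#' random center, width and height; in case samples, `n_affected` randomly
#' chosen proteins have their peak shifted by `shift` slices and scaled by
#' `abundance_factor` (the kind of complex-mass/abundance change the effect
#' size is meant to detect). Each gel then gets its own slice duplications
#' and intensity factor via [apply_warp()].
#'
#' Defaults mirror a 4-case / 5-control, 60-slice, 3-gel design with 10 of
#' 100 proteins shifted by 4 slices and 3-fold up in cases, lognormal noise
#' cv 0.1 and dropout 0.02.
#'
#' @param n_case,n_control Group sizes (>= 2 each for HES).
#' @param n_proteins,n_slices Matrix geometry.
#' @param n_affected Number of case-shifted proteins.
#' @param shift Signed migration shift (slices) applied in cases.
#' @param abundance_factor Peak-height factor applied in cases.
#' @param noise_cv,dropout_p Passed to [generate_profile()].
#' @param n_gels Number of gels; samples are assigned round-robin.
#' @param gel_insertions List (length `n_gels`) of duplicated original-slice
#'   positions per gel; default: none / (15, 40) / (25, 50) recycled.
#' @param gel_factors Per-gel intensity factors; default 1 / 1.3 / 0.8.
#' @param seed Integer seed fixing all randomness.
#' @return List with `profiles` (list of warped `cx_profile`), `groups`
#'   (`cx_groups`), and `truth`: `affected` ids, `base_peaks` data.frame,
#'   `gel_of` (named integer), `warps` (per-sample insert positions),
#'   `factors` (per-sample), `shift`, `abundance_factor`.
#' @export
generate_study <- function(n_case = 4L, n_control = 5L, n_proteins = 100L,
                           n_slices = 60L, n_affected = 10L, shift = 4L,
                           abundance_factor = 3, noise_cv = 0.1,
                           dropout_p = 0.02, n_gels = 3L,
                           gel_insertions = NULL, gel_factors = NULL,
                           seed = 1L) {
  stopifnot(n_case >= 2L, n_control >= 2L, n_affected <= n_proteins)
  if (is.null(gel_insertions)) {
    # fractions of the lane; at 60 slices: none / (15, 40) / (25, 50)
    frac <- list(numeric(0), c(0.25, 2 / 3), c(5 / 12, 5 / 6))
    gel_insertions <- lapply(rep(frac, length.out = n_gels),
                             function(f) as.integer(round(f * n_slices)))
  }
  if (is.null(gel_factors))
    gel_factors <- rep(c(1, 1.3, 0.8), length.out = n_gels)
  stopifnot(length(gel_insertions) == n_gels,
            length(gel_factors) == n_gels)

  set.seed(as.integer(seed))
  roster <- sprintf("P%03d", seq_len(n_proteins))
  base_peaks <- data.frame(
    protein_id = roster,
    center = stats::runif(n_proteins, 0.15 * n_slices, 0.85 * n_slices),
    width = stats::runif(n_proteins, 1.5, 3),
    height = 10^stats::runif(n_proteins, 3, 6))
  affected <- sort(sample(roster, n_affected))

  ids <- c(sprintf("case_%d", seq_len(n_case)),
           sprintf("ctrl_%d", seq_len(n_control)))
  is_case <- c(rep(TRUE, n_case), rep(FALSE, n_control))
  gel_of <- stats::setNames(rep(seq_len(n_gels), length.out = length(ids)),
                            ids)
  sample_seeds <- (as.integer(seed) + 7919L * seq_along(ids)) %%
    .Machine$integer.max

  profiles <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pk <- base_peaks
    if (is_case[i] && n_affected > 0L) {
      hit <- pk$protein_id %in% affected
      pk$center[hit] <- pk$center[hit] + shift
      pk$height[hit] <- pk$height[hit] * abundance_factor
    }
    prof <- generate_profile(ids[i], roster, n_slices, pk,
                             noise_cv = noise_cv, dropout_p = dropout_p,
                             seed = sample_seeds[i])
    g <- gel_of[i]
    profiles[[i]] <- apply_warp(prof, gel_insertions[[g]], gel_factors[g])
  }
  names(profiles) <- ids
  list(profiles = profiles,
       groups = new_groups(ids[is_case], ids[!is_case]),
       truth = list(affected = affected, base_peaks = base_peaks,
                    gel_of = gel_of,
                    warps = stats::setNames(
                      lapply(ids, function(s) gel_insertions[[gel_of[s]]]),
                      ids),
                    factors = stats::setNames(gel_factors[gel_of], ids),
                    shift = shift, abundance_factor = abundance_factor))
}
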