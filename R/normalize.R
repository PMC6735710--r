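#' Sum-equalization normalization across samples
#'
#' Corrects for overall intensity differences between gels: each sample's
#' matrix is multiplied by one scalar so that the summed intensity over the
#' analysis roster is identical across samples. The roster is whatever the
#' profile set was restricted to (harmonize/subset first); all-zero rows do
#' not change sums, so zero-filling before normalizing is safe.
#'
#' @param profile_set A `cx_profile_set`.
#' @param target `"mean"` (default: the mean of the per-sample raw sums,
#'   keeping values in the input's order of magnitude) or `"fixed"`.
#' @param value Target sum when `target = "fixed"`.
#' @return List with `profile_set` (normalized) and `report`, a data.frame
#'   with per-sample raw sum, scale factor and the common target sum.
#' @export
normalize_sum <- function(profile_set, target = c("mean", "fixed"),
                          value = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(profile_set, "cx_profile_set"))
  sums <- vapply(profile_set$profiles,
                 function(p) sum(p$intensities), numeric(1))
  zero <- names(sums)[sums <= 0]
  if (length(zero))
    stop("sample(s) with zero total intensity over the roster: ",
         paste(zero, collapse = ", "))
  tgt <- if (target == "mean") mean(sums) else {
    if (is.null(value) || !is.finite(value) || value <= 0)
      stop("target = 'fixed' needs a positive 'value'")
    value
  }
  factors <- tgt / sums
  profiles <- mapply(function(p, f) {
    new_profile(p$sample_id, p$intensities * f, annotations = p$annotations)
  }, profile_set$profiles, factors, SIMPLIFY = FALSE)
  names(profiles) <- names(profile_set$profiles)
  report <- data.frame(sample = names(sums), raw_sum = unname(sums),
                       scale_factor = unname(factors), target_sum = tgt,
                       row.names = NULL)
  list(profile_set = structure(list(profiles = profiles,
                                    protein_ids = profile_set$protein_ids),
                               class = "cx_profile_set"),
       report = report)
}
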