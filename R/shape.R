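#' Anatomical shape prior
#'
#' The voxelwise average of the training-fold binary masks on the common
#' kidney-centred ROI lattice: `S(x)` is the fraction of training subjects
#' whose mask labels voxel `x` as kidney. Voxels consistently labelled
#' kidney approach 1, background approaches 0, and anatomically variable
#' boundary regions take intermediate values. The prior is recomputed per
#' cross-validation fold (and per modality) from reference masks only.
#'
#' @param masks list of [binary_mask()]s on a common lattice.
#' @return object of class `shape_prior`: list with `s` (numeric array in
#'   `[0, 1]`) and `n_subjects`.
#' @export
shape_prior <- function(masks) {
  if (length(masks) < 1L) stop("at least one mask is required")
  d <- dim(masks[[1]])
  s <- array(0, d)
  for (m in masks) {
    if (!identical(dim(m), d)) stop("mask shape mismatch")
    s <- s + array(as.double(m), d)
  }
  s <- s / length(masks)
  structure(list(s = s, n_subjects = length(masks)), class = "shape_prior")
}

#' @export
print.shape_prior <- function(x, ...) {
  cat(sprintf("shape_prior over %d subjects; occupancy mass %.1f voxels, max %.3f\n",
              x$n_subjects, sum(x$s), max(x$s)))
  invisible(x)
}

#' Binarize a shape prior
#'
#' Thresholds the mask-frequency field at `tau`; ties at exactly `tau`
#' resolve to foreground, matching the 0.5 threshold convention used for the
#' network output. The binarized prior supplies the inference-time band
#' reference for the appearance map.
#'
#' @param prior a [shape_prior()].
#' @param tau threshold in `[0, 1]` (default 0.5).
#' @return a [binary_mask()].
#' @export
binarize_prior <- function(prior, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  binary_mask(array(as.integer(prior$s >= tau), dim(prior$s)))
}
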