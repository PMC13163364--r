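check_same_lattice <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("mask shape mismatch")
}

#' Dice similarity coefficient
#'
#' `2|P intersect R| / (|P| + |R|)`; two empty masks score 1 by convention.
#'
#' @param pred,ref [binary_mask()]s on the same lattice.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  check_same_lattice(pred, ref)
  np <- sum(pred); nr <- sum(ref)
  if (np + nr == 0) return(1)
  2 * sum(pred == 1L & ref == 1L) / (np + nr)
}

#' Intersection over union (Jaccard index)
#'
#' `|P intersect R| / |P union R|`; two empty masks score 1 by convention.
#'
#' @inheritParams dice
#' @return fraction in `[0, 1]`.
#' @export
iou <- function(pred, ref) {
  check_same_lattice(pred, ref)
  u <- sum(pred == 1L | ref == 1L)
  if (u == 0) return(1)
  sum(pred == 1L & ref == 1L) / u
}

#' Pooled symmetric surface distances
#'
#' For every boundary voxel of the prediction, the distance in mm to the
#' nearest boundary voxel of the reference, and vice versa, pooled into one
#' sorted list. Boundary voxels are foreground voxels with at least one
#' face-adjacent background neighbour (the volume faces count as
#' background); distances use the anisotropic voxel spacing and masks are
#' never resampled.
#'
#' @inheritParams dice
#' @param spacing voxel spacing in mm along (z, y, x).
#' @return sorted numeric vector of distances in mm.
#' @export
surface_distances <- function(pred, ref, spacing = c(1, 1, 1)) {
  check_same_lattice(pred, ref)
  if (sum(pred) == 0 || sum(ref) == 0)
    stop("undefined surface distance: empty mask")
  sort(cpp_surface_distances(as.integer(pred), as.integer(ref), dim(pred),
                             as.numeric(spacing)))
}

#' 95th percentile Hausdorff distance (mm)
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' the pooled symmetric surface-distance list.
#'
#' @inheritParams surface_distances
#' @return distance in mm.
#' @export
hd95 <- function(pred, ref, spacing = c(1, 1, 1)) {
  d <- surface_distances(pred, ref, spacing)
  quantile(d, 0.95, type = 7, names = FALSE)
}

#' Average symmetric surface distance (mm)
#'
#' Mean of the pooled symmetric surface-distance list.
#'
#' @inheritParams surface_distances
#' @return distance in mm.
#' @export
assd <- function(pred, ref, spacing = c(1, 1, 1)) {
  mean(surface_distances(pred, ref, spacing))
}

#' All four segmentation scores
#'
#' Dice and IoU (volumetric overlap) plus HD95 and ASSD (boundary accuracy,
#' mm). When either mask is empty the surface metrics are undefined: they
#' are returned as `NA` with `flagged = TRUE` so the cross-validation
#' harness can record and exclude the case.
#'
#' @inheritParams surface_distances
#' @return one-row `data.frame` with columns `dice`, `iou`, `hd95`, `assd`,
#'   `flagged`.
#' @export
seg_scores <- function(pred, ref, spacing = c(1, 1, 1)) {
  ds <- dice(pred, ref)
  jc <- iou(pred, ref)
  if (sum(pred) == 0 || sum(ref) == 0) {
    data.frame(dice = ds, iou = jc, hd95 = NA_real_, assd = NA_real_,
               flagged = TRUE)
  } else {
    d <- surface_distances(pred, ref, spacing)
    data.frame(dice = ds, iou = jc,
               hd95 = quantile(d, 0.95, type = 7, names = FALSE),
               assd = mean(d), flagged = FALSE)
  }
}
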