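#' 3D image volume on a voxel lattice
#'
#' A `grid_volume` is a 3D scalar field with axis order (z, y, x) — the
#' first array dimension is the slice axis — together with the voxel spacing
#' in millimetres per axis. Voxel indices are 1-based throughout the package.
#'
#' @param data numeric 3D array, dimensions (D, H, W) = (slices, rows, cols).
#' @param spacing positive numeric length-3, mm per voxel along (z, y, x).
#' @param subject optional subject identifier tag.
#' @return An object of class `grid_volume`: the array with `spacing` and
#'   `subject` attributes.
#' @examples
#' v <- grid_volume(array(rnorm(4 * 8 * 8), c(4, 8, 8)), spacing = c(4, 0.72, 0.72))
#' dim(v)
#' @export
grid_volume <- function(data, spacing = c(1, 1, 1), subject = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  structure(data, spacing = spacing, subject = subject,
            class = c("grid_volume", "array"))
}

#' Binary segmentation mask
#'
#' A `{0,1}` field on the same lattice convention as [grid_volume()].
#'
#' @param data array or logical array with values exactly 0 or 1.
#' @return An object of class `binary_mask` (integer array).
#' @export
binary_mask <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D mask")
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    if (!all(data %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
    storage.mode(data) <- "integer"
  }
  structure(data, class = c("binary_mask", "array"))
}

#' @export
print.grid_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("grid_volume %dx%dx%d (z,y,x), spacing %.3g x %.3g x %.3g mm",
              d[1], d[2], d[3], attr(x, "spacing")[1], attr(x, "spacing")[2],
              attr(x, "spacing")[3]))
  if (!is.null(attr(x, "subject"))) cat(", subject", attr(x, "subject"))
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("binary_mask %dx%dx%d, %d foreground voxels (%.2f%%)\n",
              d[1], d[2], d[3], sum(x), 100 * mean(x)))
  invisible(x)
}

#' Voxel spacing accessor
#' @param x a [grid_volume()].
#' @return numeric length-3 spacing in mm.
#' @export
spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

round_half_up <- function(x) floor(x + 0.5)

#' Centroid of a binary mask
#'
#' Arithmetic mean of the foreground voxel indices, rounded half-up to the
#' nearest integer voxel. The centroid anchors the kidney-centred ROI and the
#' contour-band geometry.
#'
#' @param mask a [binary_mask()].
#' @return integer length-3 voxel index (z, y, x), 1-based.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: centroid undefined")
  as.integer(round_half_up(colMeans(idx)))
}

#' Extract a fixed-size region of interest
#'
#' Crops `size` voxels centred on `center`, zero-padding wherever the crop
#' exceeds the volume bounds, so that every subject of a cohort lands on an
#' identically shaped lattice. In training mode the centre is the mask
#' centroid; at inference a centre must be supplied externally (the
#' cross-validation harness uses the cohort-mean training centroid).
#'
#' @param vol a [grid_volume()].
#' @param size integer length-3 target dimensions (D, H, W).
#' @param center integer length-3 voxel index; defaults to
#'   `mask_centroid(mask)` when a mask is given.
#' @param mask optional [binary_mask()] paired with `vol`; cropped
#'   identically when present.
#' @return list with elements `volume`, `mask` (or `NULL`), `center`, and
#'   `offset` (1-based index in the original volume of the crop's first
#'   voxel, possibly non-positive when padding was needed).
#' @export
extract_roi <- function(vol, size, center = NULL, mask = NULL) {
  size <- as.integer(size)
  if (length(size) != 3L || any(size < 1L)) stop("size must be three positive integers")
  if (is.null(center)) {
    if (is.null(mask)) stop("either center or a non-empty mask is required")
    center <- mask_centroid(mask)
  }
  center <- as.integer(center)
  d <- dim(vol)
  start <- center - size %/% 2L
  out <- array(0, size)
  om <- if (!is.null(mask)) array(0L, size) else NULL
  # overlap of [start, start+size-1] with [1, d]
  lo <- pmax(start, 1L)
  hi <- pmin(start + size - 1L, d)
  if (all(lo <= hi)) {
    src <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    dst <- list(src[[1]] - start[1] + 1L, src[[2]] - start[2] + 1L,
                src[[3]] - start[3] + 1L)
    out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
    if (!is.null(mask))
      om[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  }
  list(volume = grid_volume(out, spacing(vol), attr(vol, "subject")),
       mask = if (!is.null(om)) binary_mask(om) else NULL,
       center = center, offset = start)
}

#' Paste an ROI-frame mask back into the original volume frame
#'
#' @param mask a [binary_mask()] on the ROI lattice.
#' @param dims dimensions of the original volume.
#' @param offset the `offset` element returned by [extract_roi()].
#' @return a [binary_mask()] with dimensions `dims`.
#' @export
uncrop_mask <- function(mask, dims, offset) {
  out <- array(0L, dims)
  size <- dim(mask)
  lo <- pmax(offset, 1L)
  hi <- pmin(offset + size - 1L, dims)
  if (all(lo <= hi)) {
    dst <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    src <- list(dst[[1]] - offset[1] + 1L, dst[[2]] - offset[2] + 1L,
                dst[[3]] - offset[3] + 1L)
    out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  }
  binary_mask(out)
}

#' Min-max intensity quantization
#'
#' Rescales a volume to the integer gray levels `{0, ..., levels - 1}`. The
#' contour-band histograms index integer levels, and the gray-level
#' fallback expansion (I +/- delta) presumes an integer intensity scale, so
#' quantization to 8 bits is applied before any appearance modelling. A
#' constant volume maps to all zeros by convention.
#'
#' @param vol a [grid_volume()].
#' @param levels number of gray levels (default 256).
#' @return a [grid_volume()] with integer-valued data in `[0, levels - 1]`
#'   and a `levels` attribute.
#' @export
normalize_intensity <- function(vol, levels = 256L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  r <- range(vol)
  if (r[1] == r[2]) {
    q <- array(0, dim(vol))
  } else {
    q <- round_half_up((vol - r[1]) / (r[2] - r[1]) * (levels - 1))
  }
  out <- grid_volume(q, spacing(vol), attr(vol, "subject"))
  attr(out, "levels") <- levels
  out
}
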