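#' Partition slices into iso-contour bands
#'
#' For every slice with a non-empty reference mask, each in-plane pixel is
#' assigned to a concentric band around the mask boundary: band
#' `ceil(d / thickness)` where `d` is the unsigned in-plane Euclidean
#' distance (voxel units) to the nearest boundary pixel. Pixels on the
#' boundary itself (`d = 0`) fall in band 1; bands are capped at `n_bands`,
#' and extend on both sides of the contour so that background intensity
#' statistics can be modelled per band as well. Slices whose reference mask
#' is empty are left unassigned (label 0).
#'
#' @param mask reference [binary_mask()], non-empty on at least one slice.
#' @param n_bands number of bands (default 8).
#' @param thickness band thickness in in-plane voxels (default 1).
#' @return object of class `contour_bands`: list with `band` (integer array,
#'   0 = unassigned), `n_bands`, `thickness`.
#' @export
band_partition <- function(mask, n_bands = 8L, thickness = 1) {
  if (n_bands < 1L) stop("n_bands must be >= 1")
  if (thickness < 1) stop("thickness must be >= 1")
  if (sum(mask) == 0L) stop("reference mask is empty on every slice")
  band <- cpp_band_partition(as.integer(mask), dim(mask), as.integer(n_bands),
                             as.numeric(thickness))
  structure(list(band = band, n_bands = as.integer(n_bands),
                 thickness = thickness),
            class = "contour_bands")
}

#' @export
print.contour_bands <- function(x, ...) {
  cat(sprintf("contour_bands: %d bands, thickness %g; %d assigned voxels\n",
              x$n_bands, x$thickness, sum(x$band > 0L)))
  invisible(x)
}

#' Neighbourhood intensity response
#'
#' For each banded voxel, the total quantized intensity over the 3D
#' neighbourhood of same-band voxels within in-plane Chebyshev `radius` on
#' slices z-1, z, z+1 (out-of-volume slices contribute nothing), together
#' with the count of contributing voxels. The histogram stage divides the
#' sum by the count (rounded half-up) so that responses stay on the
#' quantized gray-level scale regardless of neighbourhood occupancy.
#'
#' @param vol quantized [grid_volume()] (see [normalize_intensity()]).
#' @param bands a `contour_bands` object on the same lattice.
#' @param radius in-plane Chebyshev radius in voxels (default 1).
#' @return object of class `neighborhood_response`: list with integer arrays
#'   `phi` (sums) and `count`.
#' @export
neighborhood_response <- function(vol, bands, radius = 1L) {
  if (!identical(dim(vol), dim(bands$band))) stop("lattice mismatch")
  r <- cpp_phi(as.integer(vol), bands$band, dim(vol), as.integer(radius))
  structure(list(phi = r$phi, count = r$count, radius = as.integer(radius)),
            class = "neighborhood_response")
}

# response levels on the quantized scale; 0 count (unassigned) -> NA
response_level <- function(resp) {
  lev <- array(NA_integer_, dim(resp$phi))
  sel <- resp$count > 0L
  lev[sel] <- as.integer(round_half_up(resp$phi[sel] / resp$count[sel]))
  lev
}

#' Fit the contour-band appearance model
#'
#' Accumulates per-band foreground/background histograms of neighbourhood
#' intensity responses over a training cohort. For every banded voxel of
#' every subject, the response level increments the foreground histogram of
#' its band when the ground-truth mask labels the voxel kidney, and the
#' background histogram otherwise; counts are summed over subjects.
#'
#' @param volumes list of quantized [grid_volume()]s.
#' @param masks list of paired [binary_mask()]s (ground truth; also the band
#'   reference for each training subject).
#' @param n_bands,thickness,radius band geometry and neighbourhood radius.
#' @param levels number of gray levels the volumes are quantized to.
#' @param delta_max maximum gray-level tolerance of the likelihood fallback.
#' @return object of class `appearance_model` with `hist_fg`, `hist_bg`
#'   (`n_bands x levels` integer matrices), and the geometry metadata.
#' @export
fit_appearance <- function(volumes, masks, n_bands = 8L, thickness = 1,
                           radius = 1L, levels = 256L, delta_max = 3L) {
  if (length(volumes) < 1L) stop("at least one training pair is required")
  if (length(volumes) != length(masks)) stop("volumes and masks differ in length")
  n_bands <- as.integer(n_bands)
  levels <- as.integer(levels)
  hf <- hb <- matrix(0L, n_bands, levels)
  for (i in seq_along(volumes)) {
    vol <- volumes[[i]]
    mask <- masks[[i]]
    if (!identical(dim(vol), dim(mask))) stop("lattice mismatch in pair ", i)
    if (any(vol < 0) || any(vol > levels - 1L) || any(vol != floor(vol)))
      stop("volume ", i, " is not quantized to {0..levels-1}")
    bands <- band_partition(mask, n_bands, thickness)
    resp <- neighborhood_response(vol, bands, radius)
    lev <- response_level(resp)
    sel <- bands$band > 0L
    key <- bands$band[sel] + n_bands * lev[sel]  # 1-based over bands x levels
    fg <- mask[sel] == 1L
    hf <- hf + matrix(tabulate(key[fg], nbins = n_bands * levels), n_bands, levels)
    hb <- hb + matrix(tabulate(key[!fg], nbins = n_bands * levels), n_bands, levels)
  }
  structure(list(hist_fg = hf, hist_bg = hb, n_bands = n_bands,
                 thickness = thickness, radius = as.integer(radius),
                 levels = levels, delta_max = as.integer(delta_max),
                 neutral = 0.5, n_subjects = length(volumes)),
            class = "appearance_model")
}

#' @export
print.appearance_model <- function(x, ...) {
  cat(sprintf(paste0("appearance_model: %d bands (thickness %g), radius %d, ",
                     "%d gray levels\n  fitted on %d subject(s); %d fg / %d bg samples\n"),
              x$n_bands, x$thickness, x$radius, x$levels, x$n_subjects,
              sum(x$hist_fg), sum(x$hist_bg)))
  invisible(x)
}

#' Kidney likelihood of an intensity level within a band
#'
#' The appearance score for level `I` in band `c` is the histogram ratio
#' `H_fg / (H_fg + H_bg)`. When the level has no support, the lookup expands
#' symmetrically to `I - delta` and `I + delta` (counts of both sides pooled)
#' for `delta = 1, ..., delta_max`; if no support is found the neutral value
#' 0.5 is returned.
#'
#' @param model an [fit_appearance()] model.
#' @param level integer gray level(s) in `[0, levels - 1]`.
#' @param band band index (1-based); recycled against `level`.
#' @return likelihood value(s) in `[0, 1]`.
#' @export
likelihood <- function(model, level, band) {
  if (any(band < 1L | band > model$n_bands)) stop("band out of range")
  if (any(level < 0L | level > model$levels - 1L)) stop("level out of range")
  n <- max(length(level), length(band))
  level <- rep_len(as.integer(level), n)
  band <- rep_len(as.integer(band), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    b <- band[i]
    p <- NA_real_
    fg <- model$hist_fg[b, level[i] + 1L]
    bg <- model$hist_bg[b, level[i] + 1L]
    if (fg + bg > 0L) {
      p <- fg / (fg + bg)
    } else {
      for (delta in seq_len(model$delta_max)) {
        ii <- c(level[i] - delta, level[i] + delta)
        ii <- ii[ii >= 0L & ii <= model$levels - 1L]
        if (length(ii)) {
          fg <- sum(model$hist_fg[b, ii + 1L])
          bg <- sum(model$hist_bg[b, ii + 1L])
          if (fg + bg > 0L) { p <- fg / (fg + bg); break }
        }
      }
      if (is.na(p)) p <- model$neutral
    }
    out[i] <- p
  }
  out
}

# full (band x level) likelihood lookup table, vectorised fallback
likelihood_table <- function(model) {
  hf <- model$hist_fg
  hb <- model$hist_bg
  tot <- hf + hb
  p <- ifelse(tot > 0, hf / pmax(tot, 1L), NA_real_)
  if (anyNA(p)) {
    L <- model$levels
    for (delta in seq_len(model$delta_max)) {
      if (!anyNA(p)) break
      shift <- function(m, k) {
        out <- matrix(0, nrow(m), ncol(m))
        if (k > 0) out[, (k + 1L):L] <- m[, 1L:(L - k)]
        else out[, 1L:(L + k)] <- m[, (1L - k):L]
        out
      }
      pf <- shift(hf, delta) + shift(hf, -delta)
      pb <- shift(hb, delta) + shift(hb, -delta)
      tt <- pf + pb
      fill <- is.na(p) & tt > 0
      p[fill] <- (pf / pmax(tt, 1L))[fill]
    }
    p[is.na(p)] <- model$neutral
  }
  p
}

#' Voxelwise appearance prior map
#'
#' Evaluates the fitted appearance model on a (quantized) volume: for every
#' banded voxel, the kidney likelihood of its neighbourhood response level
#' within its band; voxels on slices without a band assignment carry the
#' neutral value 0.5. At inference the band reference comes from the
#' binarized anatomical shape prior, since the test subject has no
#' ground-truth contour.
#'
#' @param model an [fit_appearance()] model.
#' @param vol quantized [grid_volume()].
#' @param bands a `contour_bands` object for `vol`.
#' @return numeric array in `[0, 1]` with the dimensions of `vol`.
#' @export
appearance_map <- function(model, vol, bands) {
  if (!identical(dim(vol), dim(bands$band))) stop("lattice mismatch")
  if (bands$n_bands != model$n_bands)
    stop("band count differs between model and band field")
  resp <- neighborhood_response(vol, bands, model$radius)
  lev <- response_level(resp)
  out <- array(model$neutral, dim(vol))
  sel <- bands$band > 0L
  tab <- likelihood_table(model)
  out[sel] <- tab[cbind(bands$band[sel], lev[sel] + 1L)]
  out
}
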