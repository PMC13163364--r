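#' Condition volume for the adversarial network
#'
#' Ordered channel stack on one lattice. The full model uses three channels:
#' `c1` the grayscale ROI rescaled to `[0, 1]`, `c2` the appearance prior
#' map, `c3` the anatomical shape prior. Ablation configurations use a
#' single image channel (`raw`, `roi`) or duplicate the appearance map as
#' `c3` (`roi_prob`).
#'
#' @param ... numeric 3D arrays (the channels, in order), or a single list
#'   of such arrays.
#' @param names optional channel names.
#' @return object of class `condition_volume`: list with `channels` and
#'   `dims`.
#' @export
condition_volume <- function(..., names = NULL) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !is.array(ch[[1]]))
    ch <- ch[[1]]
  if (length(ch) < 1L) stop("at least one channel is required")
  d <- dim(ch[[1]])
  if (length(d) != 3L) stop("channels must be 3D arrays")
  for (i in seq_along(ch)) {
    if (!identical(dim(ch[[i]]), d)) stop("channel ", i, " shape mismatch")
    if (i > 1L && (min(ch[[i]]) < 0 || max(ch[[i]]) > 1))
      stop("prior channels must lie in [0, 1]")
  }
  structure(list(channels = lapply(ch, function(x) {
    x <- as.array(x); attributes(x) <- list(dim = d); x
  }), dims = d, names = names), class = "condition_volume")
}

#' @export
print.condition_volume <- function(x, ...) {
  cat(sprintf("condition_volume: %d channel(s) on %dx%dx%d\n",
              length(x$channels), x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Number of channels of a condition volume
#' @param cond a [condition_volume()].
#' @return integer channel count.
#' @export
n_channels <- function(cond) length(cond$channels)

# (N x C) matrix in the native voxel order (z fastest), as consumed by the
# network backend
cond_as_matrix <- function(cond) {
  do.call(cbind, lapply(cond$channels, as.vector))
}
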