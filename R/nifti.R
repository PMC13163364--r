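# Minimal NIfTI-1 input/output. No NIfTI package is available in the target
# R stack, so the single-file format (348-byte header + raw data, optionally
# gzip-compressed) is read and written directly. Dimension 1 of the stored
# image corresponds to the package's slice axis z; spacing follows the same
# order. Only plain 3D scalar images are supported.

nifti_dtypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double", size = 4L, signed = TRUE),
  `64` = list(what = "double", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3D NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file written by [write_nifti()] or any
#' single-file NIfTI-1 writer. The image must be 3D; voxel spacing is taken
#' from `pixdim` and the scaling slope/intercept are applied when set.
#'
#' @param path file path.
#' @param subject optional subject tag attached to the result.
#' @return a [grid_volume()].
#' @export
read_nifti <- function(path, subject = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header")
  sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "big")
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported")
  dims <- readBin(hdr[41:56], "integer", 8L, 2L, endian = endian)
  if (dims[1] != 3L) stop("expected 3D volume, got ", dims[1], "D")
  d <- dims[2:4]
  datatype <- readBin(hdr[71:72], "integer", 1L, 2L, endian = endian)
  spec <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- readBin(hdr[77:108], "double", 8L, 4L, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", 1L, 4L, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", 1L, 4L, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", 1L, 4L, endian = endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(d)
  vals <- readBin(con, spec$what, n, spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (!all(is.finite(vals))) stop("volume contains non-finite voxels")
  grid_volume(array(as.double(vals), d), spacing = pixdim[2:4],
              subject = subject)
}

#' Read a NIfTI-1 file as a binary mask
#'
#' @param path file path.
#' @return a [binary_mask()]; values other than 0/1 are rejected.
#' @export
read_nifti_mask <- function(path) {
  v <- read_nifti(path)
  binary_mask(array(as.numeric(v), dim(v)))
}

#' Write a volume or mask as single-file NIfTI-1
#'
#' Volumes are stored as float32, masks as uint8. Paths ending in `.gz` are
#' gzip-compressed.
#'
#' @param x a [grid_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override for masks (which carry none); volumes use
#'   their own spacing attribute.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1)) {
  is_mask <- inherits(x, "binary_mask")
  sp <- if (is_mask) spacing else spacing(x)
  d <- dim(x)
  hdr <- raw(348L)
  put <- function(value, at, what, size) {
    b <- writeBin(value, raw(), size, endian = "little")
    hdr[at:(at + length(b) - 1L)] <<- b
  }
  put(348L, 1L, "integer", 4L)
  put(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 41L, "integer", 2L)
  put(if (is_mask) 2L else 16L, 71L, "integer", 2L)           # datatype
  put(if (is_mask) 8L else 32L, 73L, "integer", 2L)           # bitpix
  put(as.numeric(c(1, sp, 0, 0, 0, 0)), 77L, "double", 4L)    # pixdim
  put(352, 109L, "double", 4L)                                # vox_offset
  put(c(1, 0), 113L, "double", 4L)                            # scl slope/inter
  hdr[124] <- as.raw(2L)                                      # xyzt_units: mm
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # pad to vox_offset 352
  if (is_mask) {
    writeBin(as.raw(as.integer(x)), con)
  } else {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}
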