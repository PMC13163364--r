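# Synthetic kidney-transplant phantoms: a single connected, optionally
# dented ("bean") ellipsoid per subject with randomised pose, contrast
# regimes mimicking the three MRI sequences, additive Gaussian noise and a
# smooth multiplicative bias field. Deterministic given (seed, index).

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

phantom_presets <- list(
  t2_like = list(fg_mean = 130, bg_mean = 100, noise_sd = 20,
                 bias_amplitude = 0.2, z_decay = 0,
                 spacing = c(6, 0.63, 0.63)),
  bold_like = list(fg_mean = 160, bg_mean = 100, noise_sd = 20,
                   bias_amplitude = 0.2, z_decay = 0.3,
                   spacing = c(3, 1.25, 1.25)),
  dw_like = list(fg_mean = 200, bg_mean = 50, noise_sd = 15,
                 bias_amplitude = 0.15, z_decay = 0,
                 spacing = c(4, 0.72, 0.72))
)

#' Phantom cohort configuration
#'
#' The modality presets encode the contrast-to-noise ordering of the three
#' renal MRI sequences this package targets: `dw_like` is high contrast
#' (|fg - bg| / noise = 10), `bold_like` intermediate (3, with a crude
#' through-slice signal-decay surrogate), `t2_like` low contrast (1.5).
#' Geometry defaults are stated for the 16 x 64 x 64 reference grid and are
#' scaled proportionally for other grid sizes.
#'
#' @param n_subjects cohort size.
#' @param grid volume dimensions (D, H, W).
#' @param modality one of `"dw_like"`, `"t2_like"`, `"bold_like"`.
#' @param semi_axes list with elements `z`, `y`, `x`: ranges (voxels) the
#'   ellipsoid semi-axes are drawn from.
#' @param rotation_range in-plane rotation range in degrees (+/-).
#' @param center_jitter maximum centre offset (voxels) per axis (z, y, x).
#' @param concavity relative size of the subtracted dent ellipsoid (0
#'   disables the bean shape).
#' @param fg_mean,bg_mean,noise_sd,bias_amplitude,z_decay,spacing intensity
#'   model; defaults come from the modality preset.
#' @param seed cohort seed.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 12L, grid = c(16L, 64L, 64L),
                           modality = c("dw_like", "t2_like", "bold_like"),
                           semi_axes = NULL, rotation_range = 25,
                           center_jitter = NULL, concavity = 0.3,
                           fg_mean = NULL, bg_mean = NULL, noise_sd = NULL,
                           bias_amplitude = NULL, z_decay = NULL,
                           spacing = NULL, seed = 1L) {
  modality <- match.arg(modality)
  p <- phantom_presets[[modality]]
  grid <- as.integer(grid)
  sc_ip <- grid[2] / 64  # in-plane geometry scale relative to reference grid
  sc_z <- grid[1] / 16
  if (is.null(semi_axes))
    semi_axes <- list(z = c(4, 6) * sc_z, y = c(12, 18) * sc_ip,
                      x = c(9, 14) * sc_ip)
  if (is.null(center_jitter))
    center_jitter <- c(1 * sc_z, 6 * sc_ip, 6 * sc_ip)
  cfg <- list(n_subjects = as.integer(n_subjects), grid = grid,
              modality = modality, semi_axes = semi_axes,
              rotation_range = rotation_range,
              center_jitter = center_jitter, concavity = concavity,
              fg_mean = fg_mean %||% p$fg_mean,
              bg_mean = bg_mean %||% p$bg_mean,
              noise_sd = noise_sd %||% p$noise_sd,
              bias_amplitude = bias_amplitude %||% p$bias_amplitude,
              z_decay = z_decay %||% p$z_decay,
              spacing = spacing %||% p$spacing, seed = as.integer(seed))
  if (cfg$fg_mean == cfg$bg_mean)
    warning("fg_mean equals bg_mean: degenerate zero-contrast phantom")
  structure(cfg, class = "phantom_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subject_seed <- function(cfg, index) {
  as.integer((as.numeric(cfg$seed) * 10007 + index * 7919) %% 2147483587)
}

#' Generate one phantom subject
#'
#' The mask is a rotated, jittered, optionally dented ellipsoid (always a
#' single face-connected component); the image is the two-level foreground/
#' background intensity model multiplied by a smooth low-frequency cosine
#' bias field plus Gaussian noise.
#'
#' @param cfg a [phantom_config()].
#' @param index subject index (1-based); `(seed, index)` determines the
#'   subject completely.
#' @return list with `volume` ([grid_volume()]), `mask` ([binary_mask()]),
#'   and `params` (the drawn pose).
#' @export
make_subject <- function(cfg, index) {
  d <- cfg$grid
  with_local_seed(subject_seed(cfg, index), {
    ax <- c(runif(1, cfg$semi_axes$z[1], cfg$semi_axes$z[2]),
            runif(1, cfg$semi_axes$y[1], cfg$semi_axes$y[2]),
            runif(1, cfg$semi_axes$x[1], cfg$semi_axes$x[2]))
    theta <- runif(1, -cfg$rotation_range, cfg$rotation_range) * pi / 180
    jit <- round(runif(3, -cfg$center_jitter, cfg$center_jitter))
    ctr <- (d + 1) / 2 + jit
    # rotation can push the in-plane extent up to the larger in-plane axis
    ax_ext <- c(ax[1], max(ax[2:3]), max(ax[2:3]))
    if (any(ctr - ax_ext < 0.5) || any(ctr + ax_ext > d + 0.5))
      stop("ellipsoid exceeds the grid; enlarge the grid or shrink the axes")
    z <- slice.index(array(0, d), 1) - ctr[1]
    y <- slice.index(array(0, d), 2) - ctr[2]
    x <- slice.index(array(0, d), 3) - ctr[3]
    yr <- cos(theta) * y + sin(theta) * x   # rotate in-plane
    xr <- -sin(theta) * y + cos(theta) * x
    inside <- (z / ax[1])^2 + (yr / ax[2])^2 + (xr / ax[3])^2 <= 1
    if (cfg$concavity > 0) {
      dent <- (z / (cfg$concavity * ax[1]))^2 +
        ((yr - 0.95 * ax[2]) / (cfg$concavity * ax[2]))^2 +
        (xr / (cfg$concavity * ax[3]))^2 <= 1
      inside <- inside & !dent
    }
    mask <- binary_mask(array(as.integer(inside), d))
    fg <- cfg$fg_mean
    if (cfg$z_decay > 0) {
      zfrac <- (slice.index(array(0, d), 1) - 1) / max(d[1] - 1, 1)
      fg <- cfg$fg_mean * (1 - cfg$z_decay * zfrac)
    }
    img <- ifelse(inside, fg, cfg$bg_mean)
    if (cfg$bias_amplitude > 0) {
      ph <- runif(3, 0, 2 * pi)
      fr <- runif(3, 0.5, 1.5)
      b <- cos(2 * pi * fr[1] * (z + ctr[1]) / d[1] + ph[1]) +
        cos(2 * pi * fr[2] * (y + ctr[2]) / d[2] + ph[2]) +
        cos(2 * pi * fr[3] * (x + ctr[3]) / d[3] + ph[3])
      img <- img * (1 + cfg$bias_amplitude * b / 3)
    }
    if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
    vol <- grid_volume(array(img, d), spacing = cfg$spacing,
                       subject = sprintf("phantom%03d", index))
    list(volume = vol, mask = mask,
         params = list(index = index, semi_axes = ax, theta = theta,
                       center = ctr))
  })
}

#' Generate a phantom cohort
#'
#' @param cfg a [phantom_config()].
#' @return object of class `phantom_cohort`: list with `subjects` (list of
#'   `(volume, mask, params)` triples), `manifest` (one row of pose
#'   parameters per subject) and `config`.
#' @export
make_cohort <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  subjects <- lapply(seq_len(cfg$n_subjects), function(i) make_subject(cfg, i))
  manifest <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject = s$params$index,
               seed = subject_seed(cfg, s$params$index),
               a_z = s$params$semi_axes[1], a_y = s$params$semi_axes[2],
               a_x = s$params$semi_axes[3],
               theta_deg = s$params$theta * 180 / pi,
               c_z = s$params$center[1], c_y = s$params$center[2],
               c_x = s$params$center[3],
               n_foreground = sum(s$mask))
  }))
  structure(list(subjects = subjects, manifest = manifest, config = cfg),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d %s subjects on %dx%dx%d\n",
              length(x$subjects), x$config$modality, x$config$grid[1],
              x$config$grid[2], x$config$grid[3]))
  invisible(x)
}

#' Contrast-to-noise ratio implied by a phantom configuration
#' @param cfg a [phantom_config()].
#' @return `|fg_mean - bg_mean| / noise_sd`.
#' @export
phantom_cnr <- function(cfg) abs(cfg$fg_mean - cfg$bg_mean) / cfg$noise_sd
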