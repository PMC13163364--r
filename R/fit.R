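band_reference_map <- function(sprior, n_bands, thickness) {
  ref <- binarize_prior(sprior, 0.5)
  if (sum(ref) == 0L) return(NULL)
  band_partition(ref, n_bands, thickness)
}

build_condition_channels <- function(c1, papp, sprior, config) {
  switch(config,
         raw = condition_volume(c1),
         roi = condition_volume(c1),
         roi_prob = condition_volume(c1, papp, papp),
         full = condition_volume(c1, papp, sprior$s),
         stop("unknown configuration: ", config))
}

#' Fit the prior-guided adversarial kidney segmenter
#'
#' The single fitting entry point: given a training cohort of grayscale
#' volumes and binary kidney masks, it (i) standardises every subject onto a
#' fixed-size kidney-centred ROI lattice, (ii) builds the contour-band
#' appearance model and the anatomical shape prior from the cohort, (iii)
#' assembles per-subject condition volumes for the requested input
#' configuration, and (iv) trains the conditional GAN. The returned object
#' predicts masks for new volumes via [predict.priorseg()].
#'
#' Input configurations mirror the ablation protocol: `"raw"` feeds the
#' full grayscale volume without spatial standardisation or priors (the
#' fully convolutional network adapts to the larger grid); `"roi"` the
#' kidney-centred crop only; `"roi_prob"` adds the
#' appearance map as channels 2 and 3; `"full"` uses (ROI, appearance map,
#' shape prior). Contour bands for the appearance channel are taken from the
#' boundary of the binarized shape prior for all subjects — the only
#' mask-free band reference available at inference time — so training and
#' test channels are computed identically and without access to the test
#' mask.
#'
#' @param volumes list of [grid_volume()]s (training cohort).
#' @param masks list of paired ground-truth [binary_mask()]s.
#' @param config input configuration (see Details).
#' @param roi_size common ROI dimensions (D, H, W); in-plane sizes must be
#'   multiples of `2^(levels - 1)` of the generator.
#' @param validation indices (into `volumes`) held aside from GAN training
#'   for per-epoch validation Dice and best-checkpoint selection; the priors
#'   still use all subjects, matching the cross-validation protocol in which
#'   priors are built from the full reference set and only the network uses
#'   the inner 80/20 split.
#' @param n_bands,thickness,radius,levels appearance-model geometry.
#' @param net a [net_control()].
#' @param train a [train_control()].
#' @param keep_conditions keep the per-subject training condition volumes on
#'   the object (for audits; off by default).
#' @return object of class `priorseg`.
#' @seealso [predict.priorseg()], [run_loocv()], [make_cohort()]
#' @examples
#' \donttest{
#' coh <- make_cohort(phantom_config(n_subjects = 4, grid = c(8, 32, 32),
#'                                   modality = "dw_like", seed = 7))
#' vols <- lapply(coh$subjects, `[[`, "volume")
#' msks <- lapply(coh$subjects, `[[`, "mask")
#' fit <- priorseg(vols[1:3], msks[1:3], roi_size = c(8, 32, 32),
#'                 net = tiny_net(), train = train_control(epochs = 2, seed = 1))
#' pred <- predict(fit, vols[[4]])
#' dice(pred, msks[[4]])
#' }
#' @export
priorseg <- function(volumes, masks,
                     config = c("full", "roi_prob", "roi", "raw"),
                     roi_size = c(16L, 64L, 64L), validation = NULL,
                     n_bands = 8L, thickness = 1, radius = 1L, levels = 256L,
                     net = net_control(), train = train_control(),
                     keep_conditions = FALSE) {
  config <- match.arg(config)
  n <- length(volumes)
  if (n < 1L) stop("at least one training pair is required")
  if (length(masks) != n) stop("volumes and masks differ in length")
  if (config == "raw") {
    # no spatial standardisation: the full (identically shaped) volumes are
    # fed to the network as-is
    for (v in volumes)
      if (!identical(dim(v), dim(volumes[[1]])))
        stop("the raw configuration requires identically shaped volumes")
    roi_size <- dim(volumes[[1]])
  }
  roi_size <- as.integer(roi_size)
  check_gen_dims(roi_size, net$levels)

  # Common kidney-centred lattice: every subject (training now, the test
  # subject later) is cropped about the cohort-mean training centroid. A
  # per-subject recentred crop would align each training mask perfectly
  # with the lattice centre while the held-out subject (whose mask must not
  # be read) cannot be recentred, teaching the network a shape prior that
  # systematically misses at inference; the common centre keeps the
  # cohort's positional variability inside the priors, where the averaged
  # mask frequency is meant to encode it.
  centered <- config != "raw"
  common_center <- if (centered) {
    ctr <- do.call(rbind, lapply(masks, mask_centroid))
    as.integer(round_half_up(colMeans(ctr)))
  } else {
    as.integer(round_half_up((dim(volumes[[1]]) + 1) / 2))
  }
  centers <- rep(list(common_center), n)
  rois <- lapply(seq_len(n), function(i)
    extract_roi(volumes[[i]], roi_size, center = centers[[i]],
                mask = masks[[i]]))
  qvols <- lapply(rois, function(r) normalize_intensity(r$volume, levels))
  rmasks <- lapply(rois, function(r) r$mask)

  app <- sprior <- bands_ref <- NULL
  papps <- NULL
  if (config %in% c("roi_prob", "full")) {
    sprior <- shape_prior(rmasks)
    app <- fit_appearance(qvols, rmasks, n_bands = n_bands,
                          thickness = thickness, radius = radius,
                          levels = levels)
    bands_ref <- band_reference_map(sprior, n_bands, thickness)
    papps <- lapply(qvols, function(q) {
      if (is.null(bands_ref)) array(0.5, roi_size)
      else appearance_map(app, q, bands_ref)
    })
  }
  conds <- lapply(seq_len(n), function(i)
    build_condition_channels(as.array(qvols[[i]]) / (levels - 1),
                             papps[[i]], sprior, config))

  validation <- as.integer(validation)
  train_idx <- setdiff(seq_len(n), validation)
  if (length(train_idx) < 1L) stop("no training subjects left after validation split")
  gw <- gan_train(conds[train_idx], rmasks[train_idx], net = net,
                  train = train, val_conds = conds[validation],
                  val_masks = rmasks[validation])

  ctr_mat <- do.call(rbind, centers)
  structure(list(
    config = config, roi_size = roi_size, levels = as.integer(levels),
    n_bands = as.integer(n_bands), thickness = thickness,
    radius = as.integer(radius),
    appearance = app, shape = sprior, bands_ref = bands_ref,
    gan = gw, n_channels = n_channels(conds[[1]]),
    inference_center = as.integer(round_half_up(colMeans(ctr_mat))),
    spacing = spacing(volumes[[1]]),
    n_subjects = n, train_idx = train_idx, validation_idx = validation,
    conditions = if (keep_conditions) conds else NULL,
    roi_masks = if (keep_conditions) rmasks else NULL
  ), class = "priorseg")
}

#' Predict a kidney mask for a new volume
#'
#' Standardises the volume onto the model's ROI lattice (centred on
#' `center`, which defaults to the cohort-mean training centroid — no mask
#' of the new subject is used), rebuilds the condition channels with the
#' stored priors, runs the generator, and thresholds the sigmoid output at
#' 0.5 (ties to foreground).
#'
#' @param object a fitted [priorseg()] model.
#' @param newdata a [grid_volume()].
#' @param center ROI centre (z, y, x); defaults to the stored inference
#'   centre (volume centre for the `"raw"` configuration).
#' @param type `"mask"` for a thresholded [binary_mask()], `"prob"` for the
#'   sigmoid volume, `"logit"` for raw generator output.
#' @param frame `"original"` pastes the prediction back into the input
#'   volume's frame; `"roi"` returns it on the ROI lattice.
#' @param ... unused.
#' @return a [binary_mask()] or numeric array, per `type`.
#' @export
predict.priorseg <- function(object, newdata, center = NULL,
                             type = c("mask", "prob", "logit"),
                             frame = c("original", "roi"), ...) {
  type <- match.arg(type)
  frame <- match.arg(frame)
  if (is.null(center)) {
    center <- if (object$config == "raw")
      as.integer(round_half_up((dim(newdata) + 1) / 2))
    else object$inference_center
  }
  roi <- extract_roi(newdata, object$roi_size, center = center)
  q <- normalize_intensity(roi$volume, object$levels)
  papp <- NULL
  if (object$config %in% c("roi_prob", "full")) {
    papp <- if (is.null(object$bands_ref)) array(0.5, object$roi_size)
    else appearance_map(object$appearance, q, object$bands_ref)
  }
  cond <- build_condition_channels(as.array(q) / (object$levels - 1), papp,
                                   object$shape, object$config)
  lg <- generator_forward(object$gan, cond)
  out <- switch(type,
                logit = lg,
                prob = 1 / (1 + exp(-lg)),
                mask = binary_mask(array(as.integer(lg >= 0), dim(lg))))
  if (frame == "original" && type == "mask")
    out <- uncrop_mask(out, dim(newdata), roi$offset)
  attr(out, "roi_center") <- center
  attr(out, "roi_offset") <- roi$offset
  out
}

#' @export
print.priorseg <- function(x, ...) {
  cat(sprintf("priorseg fit: configuration '%s' (%d channel%s), %d subjects\n",
              x$config, x$n_channels, if (x$n_channels > 1) "s" else "",
              x$n_subjects))
  cat(sprintf("  ROI %dx%dx%d, %d gray levels; generator channels %s\n",
              x$roi_size[1], x$roi_size[2], x$roi_size[3], x$levels,
              paste(net_channels(x$gan$net), collapse = "-")))
  if (!is.null(x$appearance))
    cat(sprintf("  appearance prior: %d bands, thickness %g, radius %d\n",
                x$n_bands, x$thickness, x$radius))
  if (!is.null(x$shape))
    cat(sprintf("  shape prior over %d masks\n", x$shape$n_subjects))
  h <- x$gan$history
  cat(sprintf("  trained %d epochs (lambda_rec = %g)", nrow(h),
              x$gan$train$lambda_rec))
  if (length(x$validation_idx))
    cat(sprintf("; best epoch %d, validation Dice %.3f",
                x$gan$best_epoch, x$gan$best_val_dice))
  cat("\n")
  invisible(x)
}

#' @export
summary.priorseg <- function(object, ...) {
  print(object)
  h <- object$gan$history
  cat("\nTraining history (last epoch):\n")
  print(utils::tail(h, 1), row.names = FALSE)
  if (!is.null(object$appearance)) {
    m <- object$appearance
    cat(sprintf("\nAppearance histograms: %d foreground / %d background samples over %d bands\n",
                sum(m$hist_fg), sum(m$hist_bg), m$n_bands))
  }
  invisible(object)
}

#' Plot the adversarial training history
#'
#' Left panel: discriminator loss and generator adversarial loss per epoch
#' (the dashed line marks `log 2`, the uninformative-discriminator point).
#' Right panel: L1 reconstruction term and, when a validation split was
#' used, validation Dice.
#'
#' @param x a fitted [priorseg()] model.
#' @param ... unused.
#' @export
plot.priorseg <- function(x, ...) {
  h <- x$gan$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$loss_d, type = "l", xlab = "epoch", ylab = "loss",
       main = "adversarial losses",
       ylim = range(c(h$loss_d, h$loss_g_adv), finite = TRUE))
  lines(h$epoch, h$loss_g_adv, lty = 2)
  abline(h = log(2), col = "grey", lty = 3)
  legend("topright", c("D", "G (adv)"), lty = 1:2, bty = "n")
  plot(h$epoch, h$loss_g_l1, type = "l", xlab = "epoch", ylab = "",
       main = "reconstruction / validation")
  if (any(is.finite(h$val_dice))) {
    par(new = TRUE)
    plot(h$epoch, h$val_dice, type = "l", col = 2, axes = FALSE,
         xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4, col.axis = 2)
    legend("bottomright", c("L1", "val Dice"), lty = 1, col = 1:2, bty = "n")
  }
  invisible(x)
}
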