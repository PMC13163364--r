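#' Network architecture settings
#'
#' The generator is a residual 3D U-Net: per encoder level the feature
#' channels double from `base` up to `max_channels` (the default 4-level
#' schedule is 64, 128, 256, 512), all down/upsampling uses the anisotropic
#' stride (1, 2, 2) so the slice axis is never reduced, decoding uses
#' trilinear upsampling with residual blocks, and skip connections join each
#' encoder level to the decoder. The discriminator is a conditional 3D
#' PatchGAN whose blocks double channels up to `disc_max` before a final
#' 3x3x3 convolution produces a spatial logit grid.
#'
#' @param base,max_channels,levels generator channel schedule.
#' @param disc_base,disc_max,disc_blocks discriminator schedule.
#' @return list of class `net_control`.
#' @export
net_control <- function(base = 64L, max_channels = 512L, levels = 4L,
                        disc_base = 64L, disc_max = 256L, disc_blocks = 3L) {
  stopifnot(base >= 1L, levels >= 2L, disc_blocks >= 1L)
  structure(list(base = as.integer(base), max_channels = as.integer(max_channels),
                 levels = as.integer(levels), disc_base = as.integer(disc_base),
                 disc_max = as.integer(disc_max),
                 disc_blocks = as.integer(disc_blocks)),
            class = "net_control")
}

#' Tiny network preset for CPU-scale experiments
#'
#' Same topology as the default (4 levels, stride (1,2,2), PatchGAN with 3
#' blocks) with the channel schedule shrunk to 8..64, sized for synthetic
#' phantom cohorts on a single CPU.
#'
#' @return a [net_control()].
#' @export
tiny_net <- function() {
  net_control(base = 8L, max_channels = 64L, levels = 4L,
              disc_base = 8L, disc_max = 32L, disc_blocks = 3L)
}

#' Encoder channel schedule implied by a net_control
#' @param net a [net_control()].
#' @return integer vector of per-level feature channels.
#' @export
net_channels <- function(net) {
  as.integer(pmin(net$base * 2^(seq_len(net$levels) - 1L), net$max_channels))
}

#' Optimisation settings for adversarial training
#'
#' Defaults follow the conditional-GAN training recipe used for the kidney
#' segmenter: 200 epochs of Adam at learning rate 4e-4, batch size 1, and an
#' L1 reconstruction weight `lambda_rec = 200`; Adam betas (0.5, 0.999) are
#' the conventional conditional-GAN setting.
#'
#' @param epochs,lr,batch_size,lambda_rec,beta1,beta2,eps,seed see above.
#' @return list of class `train_control`.
#' @export
train_control <- function(epochs = 200L, lr = 4e-4, batch_size = 1L,
                          lambda_rec = 200, beta1 = 0.5, beta2 = 0.999,
                          eps = 1e-8, seed = 1L) {
  stopifnot(epochs >= 1L, lr > 0, lambda_rec >= 0, batch_size == 1L)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), lambda_rec = lambda_rec,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_control")
}

gan_cfg <- function(net, train, in_channels) {
  list(in_ch = as.integer(in_channels), base = net$base,
       max_ch = net$max_channels, levels = net$levels,
       d_base = net$disc_base, d_max_ch = net$disc_max,
       d_blocks = net$disc_blocks, lr = train$lr, beta1 = train$beta1,
       beta2 = train$beta2, eps = train$eps, lambda_rec = train$lambda_rec,
       epochs = train$epochs)
}

check_gen_dims <- function(dims, levels) {
  f <- 2L^(levels - 1L)
  if (dims[2] %% f != 0L || dims[3] %% f != 0L)
    stop("in-plane dimensions (H, W) must be multiples of ", f,
         " for a ", levels, "-level generator; got ", dims[2], "x", dims[3])
}

#' Initialise generator and discriminator weights
#'
#' @param net a [net_control()].
#' @param in_channels number of condition channels (1 or 3).
#' @param seed integer seed for the weight initialisation.
#' @param train a [train_control()] (carried along for the backend).
#' @return object of class `gan_weights`.
#' @export
gan_init <- function(net = net_control(), in_channels = 3L, seed = 1L,
                     train = train_control()) {
  cfg <- gan_cfg(net, train, in_channels)
  w <- cpp_gan_init(cfg, as.integer(seed))
  structure(list(weights = w, net = net, train = train,
                 in_channels = as.integer(in_channels)),
            class = "gan_weights")
}

#' @export
print.gan_weights <- function(x, ...) {
  cat(sprintf("gan_weights: %d-channel input, generator channels %s, PatchGAN x%d\n",
              x$in_channels, paste(net_channels(x$net), collapse = "-"),
              x$net$disc_blocks))
  invisible(x)
}

#' Generator forward pass
#'
#' Maps a condition volume to a single-channel logit volume of the same
#' spatial shape (eval mode: deterministic for fixed weights).
#'
#' @param gw a [gan_weights()] object (initialised or trained).
#' @param cond a [condition_volume()] with `gw$in_channels` channels.
#' @return numeric logit array (D, H, W).
#' @export
generator_forward <- function(gw, cond) {
  if (n_channels(cond) != gw$in_channels)
    stop("condition volume has ", n_channels(cond), " channels; expected ",
         gw$in_channels)
  check_gen_dims(cond$dims, gw$net$levels)
  cfg <- gan_cfg(gw$net, gw$train, gw$in_channels)
  cpp_gen_forward(gw$weights, cfg, cond_as_matrix(cond), cond$dims)
}

#' Thresholded mask prediction
#'
#' Applies the sigmoid to the generator logits and thresholds at 0.5 (ties
#' go to foreground, i.e. logit >= 0).
#'
#' @inheritParams generator_forward
#' @return a [binary_mask()].
#' @export
predict_mask <- function(gw, cond) {
  lg <- generator_forward(gw, cond)
  binary_mask(array(as.integer(lg >= 0), dim(lg)))
}

#' Discriminator forward pass
#'
#' Concatenates the mask channel with the condition volume and returns the
#' PatchGAN spatial logit grid (in-plane resolution reduced by
#' `2^disc_blocks`, slice axis preserved).
#'
#' @param gw a [gan_weights()] object.
#' @param mask numeric array in `[0, 1]` (hard mask or sigmoid output).
#' @param cond a [condition_volume()].
#' @return numeric logit array of the grid dimensions.
#' @export
discriminator_forward <- function(gw, mask, cond) {
  if (!identical(dim(mask), cond$dims)) stop("mask/condition shape mismatch")
  f <- 2L^gw$net$disc_blocks
  if (cond$dims[2] %% f != 0L || cond$dims[3] %% f != 0L)
    stop("in-plane dimensions must be multiples of ", f,
         " for a ", gw$net$disc_blocks, "-block discriminator")
  cfg <- gan_cfg(gw$net, gw$train, gw$in_channels)
  r <- cpp_disc_forward(gw$weights, cfg, as.numeric(mask),
                        cond_as_matrix(cond), cond$dims)
  r$logits
}

#' Mean binary cross-entropy with logits
#'
#' @param logits numeric logits.
#' @param target scalar or array of targets in `[0, 1]`.
#' @return scalar loss.
#' @export
bce_with_logits <- function(logits, target) {
  z <- as.numeric(logits)
  t <- rep_len(as.numeric(target), length(z))
  mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
}

#' Discriminator objective
#'
#' `0.5 * [BCE(D(y, c), 1) + BCE(D(y_hat, c), 0)]` against grids of ones and
#' zeros matching the PatchGAN output resolution. At the uninformative point
#' (all logits zero) the loss equals `log(2)`.
#'
#' @param real_logits discriminator logits on the real mask.
#' @param fake_logits discriminator logits on the generated mask.
#' @return scalar loss.
#' @export
loss_discriminator <- function(real_logits, fake_logits) {
  0.5 * (bce_with_logits(real_logits, 1) + bce_with_logits(fake_logits, 0))
}

#' Generator objective
#'
#' Adversarial term `BCE(D(y_hat, c), 1)` plus the weighted voxelwise L1
#' reconstruction term `lambda_rec * mean(|y_hat - y|)`, where `y_hat` is
#' the sigmoid output of the generator.
#'
#' @param fake_logits discriminator logits on the generated mask.
#' @param pred generator sigmoid output.
#' @param truth ground-truth mask.
#' @param lambda_rec reconstruction weight (default 200).
#' @return scalar loss.
#' @export
loss_generator <- function(fake_logits, pred, truth, lambda_rec = 200) {
  bce_with_logits(fake_logits, 1) +
    lambda_rec * mean(abs(as.numeric(pred) - as.numeric(truth)))
}

#' Train the conditional GAN
#'
#' Alternating one discriminator step and one generator step per sample
#' (batch size 1). When validation pairs are given, the per-epoch validation
#' Dice is tracked and the returned weights are the best-validation
#' checkpoint; otherwise the final weights are returned.
#'
#' @param conds list of [condition_volume()]s (identical shapes/channels).
#' @param masks list of paired [binary_mask()]s.
#' @param net a [net_control()].
#' @param train a [train_control()]; `train$seed` drives initialisation and
#'   sample shuffling, so a fixed seed reproduces the loss history exactly.
#' @param val_conds,val_masks optional validation pairs.
#' @return a `gan_weights` object with additional elements `history`
#'   (per-epoch data frame), `best_epoch`, `final_weights`.
#' @export
gan_train <- function(conds, masks, net = net_control(),
                      train = train_control(), val_conds = list(),
                      val_masks = list()) {
  if (length(conds) < 1L) stop("at least one training pair is required")
  if (length(conds) != length(masks)) stop("conds and masks differ in length")
  inch <- n_channels(conds[[1]])
  dims <- conds[[1]]$dims
  check_gen_dims(dims, net$levels)
  cfg <- gan_cfg(net, train, inch)
  cm <- lapply(conds, cond_as_matrix)
  mm <- lapply(masks, function(m) as.numeric(m))
  vc <- lapply(val_conds, cond_as_matrix)
  vm <- lapply(val_masks, function(m) as.numeric(m))
  r <- cpp_gan_train(cfg, cm, mm, dims, train$seed, vc, vm)
  hist <- as.data.frame(r$history)
  names(hist) <- c("epoch", "loss_d", "loss_g_adv", "loss_g_l1", "val_dice")
  structure(list(weights = r$weights, final_weights = r$final_weights,
                 net = net, train = train, in_channels = inch,
                 history = hist, best_epoch = r$best_epoch,
                 best_val_dice = r$best_val_dice),
            class = "gan_weights")
}
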