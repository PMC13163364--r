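rand_cond <- function(d, nch, seed = 1) {
  set.seed(seed)
  condition_volume(lapply(seq_len(nch), function(i) array(runif(prod(d)), d)))
}

test_that("generator restores the spatial shape and is deterministic", {
  gw <- gan_init(tiny_net(), in_channels = 3, seed = 7)
  cond <- rand_cond(c(8, 24, 24), 3)
  lg <- generator_forward(gw, cond)
  expect_identical(dim(lg), c(8L, 24L, 24L))
  expect_identical(lg, generator_forward(gw, cond))

  # in-plane dimensions must be divisible by 2^(levels - 1)
  bad <- rand_cond(c(8, 20, 20), 3)
  expect_error(generator_forward(gw, bad), "multiples of 8")
  expect_error(generator_forward(gw, rand_cond(c(8, 24, 24), 1)), "channels")
})

test_that("channel schedules double up to the configured maximum", {
  expect_identical(net_channels(net_control()), c(64L, 128L, 256L, 512L))
  expect_identical(net_channels(tiny_net()), c(8L, 16L, 32L, 64L))
  expect_identical(net_channels(net_control(base = 64, max_channels = 256)),
                   c(64L, 128L, 256L, 256L))
})

test_that("discriminator emits a spatial patch grid, not a scalar", {
  gw <- gan_init(tiny_net(), in_channels = 3, seed = 7)
  cond <- rand_cond(c(8, 24, 24), 3)
  m <- array(0.0, c(8, 24, 24))
  g <- discriminator_forward(gw, m, cond)
  # three stride-(1,2,2) blocks: in-plane reduced x8, slice axis preserved
  expect_identical(dim(g), c(8L, 3L, 3L))
  expect_true(length(g) > 1)
  expect_identical(g, discriminator_forward(gw, m, cond))
  expect_error(discriminator_forward(gw, array(0, c(8, 24, 23)), cond),
               "mismatch")
})

test_that("adversarial losses match their closed forms", {
  # uninformative discriminator (all logits zero): loss is log 2
  z0 <- array(0, c(2, 2))
  expect_equal(loss_discriminator(z0, z0), log(2))

  # a perfect discriminator drives the loss to zero
  expect_equal(loss_discriminator(array(50, 4), array(-50, 4)), 0,
               tolerance = 1e-12)

  # hand-set 2x2 logit grids against the manual BCE computation
  zr <- matrix(c(0.3, -1.2, 2.0, 0.0), 2)
  zf <- matrix(c(-0.5, 0.7, -2.0, 1.5), 2)
  manual <- function(z, t) mean(log(1 + exp(-z)) * t + log(1 + exp(z)) * (1 - t))
  expect_equal(bce_with_logits(zr, 1), manual(zr, 1))
  expect_equal(bce_with_logits(zf, 0), manual(zf, 0))
  expect_equal(loss_discriminator(zr, zf),
               0.5 * (manual(zr, 1) + manual(zf, 0)))

  # generator loss: exact prediction kills the reconstruction term
  y <- array(c(0, 1, 1, 0), c(1, 2, 2))
  expect_equal(loss_generator(zf, y, y), bce_with_logits(zf, 1))
  # lambda_rec = 0 leaves the pure adversarial objective
  p <- array(c(0.2, 0.9, 0.4, 0.1), c(1, 2, 2))
  expect_equal(loss_generator(zf, p, y, lambda_rec = 0), bce_with_logits(zf, 1))
  # the reconstruction term is lambda * mean absolute error
  expect_equal(loss_generator(zf, p, y) - bce_with_logits(zf, 1),
               200 * mean(abs(p - y)))
  # defaults carried by the training configuration
  tc <- train_control()
  expect_equal(tc$lambda_rec, 200)
  expect_equal(tc$lr, 4e-4)
  expect_equal(tc$batch_size, 1L)
  expect_equal(tc$epochs, 200L)
})

test_that("mask prediction thresholds the sigmoid at 0.5, ties foreground", {
  gw <- gan_init(tiny_net(), in_channels = 1, seed = 3)
  cond <- rand_cond(c(8, 24, 24), 1)
  lg <- generator_forward(gw, cond)
  pm <- predict_mask(gw, cond)
  expect_identical(as.integer(pm), as.integer(lg >= 0))
  expect_identical(as.integer(pm), as.integer(predict_mask(gw, cond)))

  # zero out the head convolution: all logits 0 -> tie -> all foreground
  nw <- length(gw$weights$gen$w)
  gw$weights$gen$w[[nw - 1]][] <- 0  # head weights
  gw$weights$gen$w[[nw]][] <- 0      # head bias
  lg0 <- generator_forward(gw, cond)
  expect_true(all(lg0 == 0))
  expect_true(all(predict_mask(gw, cond) == 1L))
})

test_that("training is reproducible and overfits a single separable pair", {
  coh <- tiny_cohort(2, grid = c(4, 16, 16), seed = 5)
  prep <- lapply(coh$subjects, function(s) {
    q <- normalize_intensity(s$volume)
    list(cond = condition_volume(as.array(q) / 255), mask = s$mask)
  })
  conds <- lapply(prep, `[[`, "cond")
  masks <- lapply(prep, `[[`, "mask")

  tr <- train_control(epochs = 3, seed = 11)
  g1 <- gan_train(conds, masks, net = tiny_net(), train = tr)
  g2 <- gan_train(conds, masks, net = tiny_net(), train = tr)
  expect_identical(g1$history, g2$history)
  expect_identical(g1$weights, g2$weights)

  # overfit sanity: with the default lambda_rec the L1 term shrinks steadily
  # toward zero on a single pair (one update per epoch at batch size 1)
  g3 <- gan_train(conds[1], masks[1], net = tiny_net(),
                  train = train_control(epochs = 120, seed = 2))
  l1 <- g3$history$loss_g_l1
  expect_lt(mean(tail(l1, 5)), 0.5 * mean(head(l1, 5)))
  blocks <- colMeans(matrix(l1, nrow = 30))
  expect_true(all(diff(blocks) < 0))

  # validation tracking: Dice improves from the first epoch to the best one
  g4 <- gan_train(conds[1], masks[1], net = tiny_net(),
                  train = train_control(epochs = 20, seed = 2),
                  val_conds = conds[2], val_masks = masks[2])
  vd <- g4$history$val_dice
  expect_true(all(is.finite(vd)))
  expect_gt(max(vd), vd[1])
  expect_equal(g4$best_epoch, which.max(vd))
  expect_equal(g4$best_val_dice, max(vd))
})
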