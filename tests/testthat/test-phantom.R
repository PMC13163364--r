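test_that("noise-free phantoms are two-valued and partitioned by the mask", {
  cfg <- phantom_config(n_subjects = 2, grid = c(8, 32, 32),
                        modality = "dw_like", noise_sd = 0,
                        bias_amplitude = 0, fg_mean = 200, bg_mean = 50,
                        seed = 4)
  s <- make_subject(cfg, 1)
  vals <- sort(unique(as.vector(unclass(s$volume))))
  expect_identical(vals, c(50, 200))
  expect_true(all(s$volume[s$mask == 1L] == 200))
  expect_true(all(s$volume[s$mask == 0L] == 50))
})

test_that("subjects are deterministic in (seed, index) and vary across index", {
  cfg <- phantom_config(n_subjects = 3, grid = c(8, 32, 32), seed = 9)
  a <- make_subject(cfg, 2)
  b <- make_subject(cfg, 2)
  expect_identical(as.vector(unclass(a$volume)), as.vector(unclass(b$volume)))
  expect_identical(as.integer(a$mask), as.integer(b$mask))
  c2 <- make_subject(cfg, 3)
  expect_false(identical(as.integer(a$mask), as.integer(c2$mask)))
})

test_that("phantom masks are single face-connected components", {
  cfg <- phantom_config(n_subjects = 50, grid = c(8, 32, 32), seed = 21)
  for (i in seq_len(50)) {
    m <- make_subject(cfg, i)$mask
    expect_gt(sum(m), 0)
    expect_identical(priorseg:::cpp_n_components(as.integer(m), dim(m)), 1L)
  }
})

test_that("cohorts carry a manifest with per-subject pose parameters", {
  cfg <- phantom_config(n_subjects = 12, grid = c(8, 32, 32), seed = 2)
  coh <- make_cohort(cfg)
  expect_length(coh$subjects, 12)
  expect_identical(nrow(coh$manifest), 12L)
  expect_true(all(c("a_z", "a_y", "a_x", "theta_deg", "c_y") %in%
                    names(coh$manifest)))
  # jitter moves the mask centroids around
  ctrs <- t(vapply(coh$subjects, function(s) mask_centroid(s$mask), integer(3)))
  expect_gt(sd(ctrs[, 2]), 0)
  expect_gt(sd(ctrs[, 3]), 0)
})

test_that("modality presets order contrast-to-noise as dw > bold >= t2", {
  cn <- vapply(c("dw_like", "bold_like", "t2_like"),
               function(m) phantom_cnr(phantom_config(modality = m)), 1)
  expect_gt(cn[["dw_like"]], cn[["bold_like"]])
  expect_gte(cn[["bold_like"]], cn[["t2_like"]])
  # presets carry the acquisition spacings
  expect_equal(phantom_config(modality = "dw_like")$spacing, c(4, 0.72, 0.72))
  expect_equal(phantom_config(modality = "t2_like")$spacing, c(6, 0.63, 0.63))
})

test_that("the cohort shape prior peaks centrally and decays outward", {
  cfg <- phantom_config(n_subjects = 15, grid = c(8, 32, 32), seed = 31)
  coh <- make_cohort(cfg)
  sp <- shape_prior(lapply(coh$subjects, `[[`, "mask"))
  ctr <- round(dim(sp$s) / 2)
  expect_equal(sp$s[ctr[1], ctr[2], ctr[3]], 1)  # centre always covered
  expect_true(all(sp$s[, 1, ] == 0))             # grid border never covered
  expect_true(all(sp$s[, , 1] == 0))
  # graded boundary: strictly intermediate values exist
  expect_gt(sum(sp$s > 0 & sp$s < 1), 0)
})

test_that("impossible geometry is rejected", {
  expect_error(make_subject(phantom_config(grid = c(8, 20, 20), seed = 1,
                                           semi_axes = list(z = c(3, 3),
                                                            y = c(15, 15),
                                                            x = c(5, 5))), 1),
               "exceeds the grid")
})
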