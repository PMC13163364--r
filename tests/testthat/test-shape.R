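test_that("shape prior is the exact voxelwise mask average", {
  d <- c(3, 6, 6)
  m <- random_blob(d, 1)

  # N identical masks reproduce the mask exactly
  sp <- shape_prior(list(m, m, m))
  expect_identical(sp$s, array(as.double(m), d))
  expect_identical(sp$n_subjects, 3L)

  # a voxel labelled in exactly one of two masks averages to 0.5
  m2 <- array(0L, d); m2[1, 1, 1] <- 1L
  sp2 <- shape_prior(list(binary_mask(m2), binary_mask(array(0L, d))))
  expect_equal(sp2$s[1, 1, 1], 0.5)

  # random cohorts: bit-for-bit equality with the sum/N oracle
  masks <- lapply(1:5, function(i) random_blob(d, 10 + i))
  sp5 <- shape_prior(masks)
  want <- Reduce(`+`, lapply(masks, function(x) array(as.double(x), d))) / 5
  expect_identical(sp5$s, want)

  # value set is contained in {k/N}; mass conservation
  expect_true(all(sp5$s %in% (0:5 / 5)))
  expect_equal(sum(sp5$s), sum(vapply(masks, sum, 1)) / 5)

  # permutation invariance
  expect_identical(shape_prior(rev(masks))$s, sp5$s)

  # incremental recurrence: s_{N+1} = (N s_N + M) / (N + 1)
  m6 <- random_blob(d, 99)
  sp6 <- shape_prior(c(masks, list(m6)))
  expect_equal(sp6$s, (5 * sp5$s + array(as.double(m6), d)) / 6)

  expect_error(shape_prior(list()), "at least one")
  expect_error(shape_prior(list(m, random_blob(c(2, 6, 6), 1))), "mismatch")
})

test_that("binarization thresholds at tau with ties to foreground", {
  d <- c(2, 4, 4)
  ones <- binary_mask(array(1L, d))
  expect_identical(as.integer(binarize_prior(shape_prior(list(ones)))),
                   as.integer(ones))

  # a value of exactly 0.5 is included (>= convention)
  half <- shape_prior(list(ones, binary_mask(array(0L, d))))
  expect_true(all(binarize_prior(half, 0.5) == 1L))
  expect_true(all(binarize_prior(half, 0.51) == 0L))

  # random prior equals the elementwise comparison oracle
  masks <- lapply(1:4, function(i) random_blob(c(3, 7, 7), 30 + i))
  sp <- shape_prior(masks)
  for (tau in c(0.25, 0.5, 0.75))
    expect_identical(as.integer(binarize_prior(sp, tau)),
                     as.integer(sp$s >= tau))
  expect_error(binarize_prior(sp, 1.2), "tau")
})
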