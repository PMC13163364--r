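test_that("Dice and IoU follow their closed forms", {
  d <- c(4, 8, 8)
  a <- random_blob(d, 1)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)

  # disjoint non-empty masks
  b <- array(0L, d); b[1, 1, 1] <- 1L
  c2 <- array(0L, d); c2[4, 8, 8] <- 1L
  expect_equal(dice(binary_mask(b), binary_mask(c2)), 0)
  expect_equal(iou(binary_mask(b), binary_mask(c2)), 0)

  # |P| = 4, |R| = 4, |intersection| = 2
  p <- array(0L, d); p[1, 1, 1:4] <- 1L
  r <- array(0L, d); r[1, 1, 3:6] <- 1L
  expect_equal(dice(binary_mask(p), binary_mask(r)), 0.5)
  expect_equal(iou(binary_mask(p), binary_mask(r)), 2 / 6)

  # both empty scores 1 by convention; shape mismatch errors
  e <- binary_mask(array(0L, d))
  expect_equal(dice(e, e), 1)
  expect_equal(iou(e, e), 1)
  expect_error(dice(a, random_blob(c(4, 8, 9), 1)), "mismatch")

  # identity iou = dice / (2 - dice) and dice >= iou on random pairs
  for (s in 1:5) {
    x <- random_blob(d, s); y <- random_blob(d, s + 50)
    dd <- dice(x, y); jj <- iou(x, y)
    expect_equal(jj, dd / (2 - dd))
    expect_true(dd >= jj)
  }
})

test_that("surface distances match the exhaustive pairwise oracle", {
  d <- c(4, 8, 8)
  a <- random_blob(d, 3)
  expect_true(all(surface_distances(a, a) == 0))

  # two single-voxel masks three in-plane voxels apart, spacing (4, 1, 1)
  p <- array(0L, d); p[2, 4, 2] <- 1L
  r <- array(0L, d); r[2, 4, 5] <- 1L
  sd2 <- surface_distances(binary_mask(p), binary_mask(r), c(4, 1, 1))
  expect_equal(sd2, c(3, 3))

  # random masks up to 10^3 voxels: full equality with the oracle
  sp <- c(4, 1.1, 0.9)
  for (s in 1:4) {
    x <- random_blob(c(6, 10, 10), s)
    y <- random_blob(c(6, 10, 10), s + 20)
    got <- surface_distances(x, y, sp)
    expect_equal(got, oracle_surface_distances(x, y, sp))
    # symmetry under swapping
    expect_equal(got, surface_distances(y, x, sp))
  }
  expect_error(surface_distances(a, binary_mask(array(0L, d))), "empty")
})

test_that("HD95 and ASSD summarise the pooled distance list", {
  d <- c(6, 10, 10)
  a <- random_blob(d, 3)
  expect_equal(hd95(a, a), 0)
  expect_equal(assd(a, a), 0)

  p <- array(0L, d); p[2, 4, 2] <- 1L
  r <- array(0L, d); r[2, 4, 5] <- 1L
  expect_equal(assd(binary_mask(p), binary_mask(r), c(4, 1, 1)), 3)

  # percentile uses linear interpolation and sits below a single outlier
  x <- random_blob(d, 5); y <- random_blob(d, 25)
  sp <- c(2, 0.8, 0.8)
  dl <- oracle_surface_distances(x, y, sp)
  expect_equal(hd95(x, y, sp), unname(quantile(dl, 0.95, type = 7)))
  expect_equal(assd(x, y, sp), mean(dl))
  expect_true(hd95(x, y, sp) <= max(dl))

  # translated copies: Dice decays with the shift while HD95 tracks it
  base <- array(0L, d); base[2:4, 3:6, 3:6] <- 1L
  shift <- function(k) {
    m <- array(0L, d); m[2:4, 3:6, (3 + k):(6 + k)] <- 1L
    binary_mask(m)
  }
  b0 <- binary_mask(base)
  expect_true(dice(b0, shift(1)) > dice(b0, shift(2)))
  expect_equal(hd95(b0, shift(2), c(2, 1, 1)),
               unname(quantile(oracle_surface_distances(b0, shift(2), c(2, 1, 1)),
                               0.95, type = 7)))
})

test_that("seg_scores flags undefined surface metrics instead of failing", {
  d <- c(4, 8, 8)
  a <- random_blob(d, 1)
  sc <- seg_scores(a, a, c(4, 1, 1))
  expect_equal(sc$dice, 1)
  expect_equal(sc$hd95, 0)
  expect_false(sc$flagged)

  sc2 <- seg_scores(binary_mask(array(0L, d)), a, c(4, 1, 1))
  expect_true(sc2$flagged)
  expect_true(is.na(sc2$hd95) && is.na(sc2$assd))
  expect_equal(sc2$dice, 0)
})
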