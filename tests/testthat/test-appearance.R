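make_bands <- function(band, n_bands, thickness = 1) {
  structure(list(band = band, n_bands = as.integer(n_bands),
                 thickness = thickness), class = "contour_bands")
}

make_model <- function(hf, hb, levels, delta_max = 3L) {
  structure(list(hist_fg = hf, hist_bg = hb, n_bands = nrow(hf),
                 thickness = 1, radius = 1L, levels = as.integer(levels),
                 delta_max = as.integer(delta_max), neutral = 0.5,
                 n_subjects = 1L),
            class = "appearance_model")
}

test_that("band partition follows the distance-to-boundary geometry", {
  # single in-plane voxel: the voxel itself (d = 0) and its 4-neighbours
  # (d = 1) are band 1; diagonal neighbours (d = sqrt(2)) band 2
  d <- c(1L, 7L, 7L)
  m <- array(0L, d); m[1, 4, 4] <- 1L
  b <- band_partition(binary_mask(m), n_bands = 8, thickness = 1)
  expect_identical(b$band[1, 4, 4], 1L)
  expect_identical(b$band[1, 3, 4], 1L)
  expect_identical(b$band[1, 4, 5], 1L)
  expect_identical(b$band[1, 3, 3], 2L)
  # capping: distance 3.2 voxels with 3 bands
  b3 <- band_partition(binary_mask(m), n_bands = 3, thickness = 1)
  expect_identical(b3$band[1, 4, 1], 3L)  # d = 3
  expect_identical(b3$band[1, 1, 1], 3L)  # d = 4.24, capped
  expect_error(band_partition(binary_mask(m), n_bands = 0), "n_bands")
  expect_error(band_partition(binary_mask(m), thickness = 0.2), "thickness")

  # full-field equality against the brute-force oracle on random blobs
  for (seed in 1:3) {
    mk <- random_blob(c(3, 10, 10), seed)
    got <- band_partition(mk, n_bands = 4, thickness = 1.5)
    expect_identical(got$band, oracle_bands(mk, 4, 1.5))
  }
})

test_that("slices with an empty reference stay unassigned", {
  d <- c(3L, 6L, 6L)
  m <- array(0L, d); m[2, 3:4, 3:4] <- 1L
  b <- band_partition(binary_mask(m), n_bands = 4, thickness = 1)
  expect_true(all(b$band[1, , ] == 0L))
  expect_true(all(b$band[3, , ] == 0L))
  expect_true(all(b$band[2, , ] > 0L))
})

test_that("neighbourhood responses sum same-band intensities across slices", {
  # isolated banded voxel: response is its own intensity
  d <- c(3L, 5L, 5L)
  band <- array(0L, d); band[2, 3, 3] <- 1L
  vol <- grid_volume(array(7, d))
  r <- neighborhood_response(vol, make_bands(band, 4), radius = 1)
  expect_identical(r$phi[2, 3, 3], 7L)
  expect_identical(r$count[2, 3, 3], 1L)
  expect_identical(r$phi[1, 1, 1], 0L)

  # three vertically stacked same-band voxels, intensities 1, 2, 3
  band2 <- array(0L, d); band2[1:3, 3, 3] <- 1L
  vol2 <- grid_volume(array(0, d)); vol2[1:3, 3, 3] <- 1:3
  r2 <- neighborhood_response(vol2, make_bands(band2, 4), radius = 1)
  expect_identical(r2$phi[2, 3, 3], 6L)

  # random toy volume equals the exhaustive triple-loop oracle
  set.seed(9)
  d3 <- c(3L, 8L, 8L)
  vol3 <- grid_volume(array(as.double(sample(0:15, prod(d3), TRUE)), d3))
  band3 <- array(sample(0:3, prod(d3), TRUE), d3)
  got <- neighborhood_response(vol3, make_bands(band3, 3), radius = 1)
  want <- oracle_phi(vol3, band3, 1)
  expect_identical(got$phi, want$phi)
  expect_identical(got$count, want$count)
})

test_that("histogram accumulation matches exhaustive counting and is additive", {
  coh <- toy_cohort(2, levels = 16)
  vols <- lapply(coh, `[[`, "volume"); masks <- lapply(coh, `[[`, "mask")
  m <- fit_appearance(vols, masks, n_bands = 4, thickness = 1, radius = 1,
                      levels = 16)
  want <- oracle_histograms(vols, masks, 4, 1, 1, 16)
  expect_identical(unname(m$hist_fg), unname(want$fg))
  expect_identical(unname(m$hist_bg), unname(want$bg))

  # conservation: per band, total mass = number of banded voxels seen
  for (i in 1:2) {
    b <- oracle_bands(masks[[i]], 4, 1)
    if (i == 1) tot <- tabulate(b[b > 0], 4) else tot <- tot + tabulate(b[b > 0], 4)
  }
  expect_identical(rowSums(m$hist_fg + m$hist_bg), as.double(tot))

  # duplicating the training set doubles every count
  m2 <- fit_appearance(c(vols, vols), c(masks, masks), n_bands = 4,
                       thickness = 1, radius = 1, levels = 16)
  expect_identical(m2$hist_fg, m$hist_fg + m$hist_fg)
  expect_identical(m2$hist_bg, 2L * m$hist_bg)

  # subject order is irrelevant
  m3 <- fit_appearance(rev(vols), rev(masks), n_bands = 4, thickness = 1,
                       radius = 1, levels = 16)
  expect_identical(m3$hist_fg, m$hist_fg)
  expect_identical(m3$hist_bg, m$hist_bg)
  expect_error(fit_appearance(list(), list()), "at least one")
})

test_that("likelihood implements the histogram ratio with delta fallback", {
  L <- 64L
  hf <- hb <- matrix(0L, 2, L)
  hf[1, 11] <- 3L; hb[1, 11] <- 1L          # level 10: 3 fg / 1 bg
  hf[1, 23] <- 2L; hb[1, 23] <- 2L          # level 22, only delta = 2 support
  hf[2, 41] <- 1L                           # asymmetric pooling check
  hb[2, 45] <- 1L                           # levels 40 and 44 around 42
  m <- make_model(hf, hb, L)

  expect_equal(likelihood(m, 10, 1), 0.75)
  # no support at 30 or 30 +/- 1..3: neutral 0.5
  expect_equal(likelihood(m, 30, 1), 0.5)
  # level 20: nothing at 19/21 (delta 1), pooled support at 22 (delta 2)
  expect_equal(likelihood(m, 20, 1), 0.5)
  # pooling is joint over both sides: at level 42, delta = 2 pools
  # {40: 1 fg} and {44: 1 bg} -> 0.5, not the first-found side alone
  expect_equal(likelihood(m, 42, 2), 0.5)
  expect_equal(likelihood(m, 43, 2), 0)  # delta 1 reaches the bg count at 44
  expect_equal(likelihood(m, 39, 2), 1)  # delta 1 reaches the fg count at 40
  expect_error(likelihood(m, 10, 3), "band")
  expect_error(likelihood(m, L, 1), "level")

  # swapping fg and bg histograms maps p to 1 - p
  msw <- make_model(hb, hf, L)
  for (lev in c(10, 22, 30, 42)) {
    expect_equal(likelihood(msw, lev, 1), 1 - likelihood(m, lev, 1))
    expect_equal(likelihood(msw, lev, 2), 1 - likelihood(m, lev, 2))
  }

  # bounded in [0, 1] on random histograms, and the lookup table agrees
  set.seed(4)
  hfr <- matrix(rpois(2 * L, 0.2), 2, L)
  hbr <- matrix(rpois(2 * L, 0.2), 2, L)
  mr <- make_model(hfr, hbr, L)
  tab <- priorseg:::likelihood_table(mr)
  for (b in 1:2) {
    p <- likelihood(mr, 0:(L - 1), b)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(tab[b, ]), p)
  }
})

test_that("appearance map composes bands, responses and likelihoods", {
  # separable limit: half-space mask, foreground level 255, background 0;
  # every banded voxel scores exactly its class label
  d <- c(2L, 8L, 8L)
  m <- array(0L, d); m[, 4:8, ] <- 1L
  mask <- binary_mask(m)
  v <- array(0, d); v[m == 1L] <- 255
  vol <- grid_volume(v); attr(vol, "levels") <- 256L
  model <- fit_appearance(list(vol), list(mask), n_bands = 4, thickness = 1,
                          radius = 1, levels = 256)
  bands <- band_partition(mask, 4, 1)
  pm <- appearance_map(model, vol, bands)
  expect_true(all(pm[m == 1L] == 1))
  expect_true(all(pm[m == 0L] == 0))

  # all-unassigned band field: uniform neutral map
  pm0 <- appearance_map(model, vol, make_bands(array(0L, d), 4))
  expect_true(all(pm0 == 0.5))

  # toy cohort: map equals the voxelwise composition of the stage oracles
  coh <- toy_cohort(3, levels = 16, seed = 11)
  vols <- lapply(coh, `[[`, "volume"); masks <- lapply(coh, `[[`, "mask")
  model2 <- fit_appearance(vols, masks, n_bands = 3, thickness = 1,
                           radius = 1, levels = 16)
  bands2 <- band_partition(masks[[1]], 3, 1)
  got <- appearance_map(model2, vols[[1]], bands2)
  r <- oracle_phi(vols[[1]], bands2$band, 1)
  want <- array(0.5, dim(vols[[1]]))
  sel <- which(bands2$band > 0)
  lev <- floor(r$phi[sel] / r$count[sel] + 0.5)
  want[sel] <- likelihood(model2, lev, bands2$band[sel])
  expect_equal(got, want)
})
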