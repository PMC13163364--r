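# Brute-force oracles and tiny fixture builders, independent of the package
# internals they are checked against.

# unsigned in-plane distance-to-boundary band labels, slice by slice
oracle_bands <- function(mask, n_bands, thickness) {
  d <- dim(mask)
  out <- array(0L, d)
  for (z in seq_len(d[1])) {
    sl <- mask[z, , , drop = TRUE]
    dim(sl) <- d[2:3]
    if (sum(sl) == 0) next
    bd <- NULL
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (sl[y, x] != 1) next
      nb <- c(if (y > 1) sl[y - 1, x] else 0L, if (y < d[2]) sl[y + 1, x] else 0L,
              if (x > 1) sl[y, x - 1] else 0L, if (x < d[3]) sl[y, x + 1] else 0L)
      if (any(nb == 0)) bd <- rbind(bd, c(y, x))
    }
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      dd <- sqrt(min((y - bd[, 1])^2 + (x - bd[, 2])^2))
      out[z, y, x] <- as.integer(min(max(ceiling(dd / thickness), 1), n_bands))
    }
  }
  out
}

# neighbourhood response by exhaustive triple loop
oracle_phi <- function(vol, band, radius) {
  d <- dim(vol)
  phi <- cnt <- array(0L, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    b <- band[z, y, x]
    if (b == 0) next
    s <- 0L; n <- 0L
    for (zz in max(1, z - 1):min(d[1], z + 1))
      for (yy in max(1, y - radius):min(d[2], y + radius))
        for (xx in max(1, x - radius):min(d[3], x + radius))
          if (band[zz, yy, xx] == b) { s <- s + vol[zz, yy, xx]; n <- n + 1L }
    phi[z, y, x] <- as.integer(s); cnt[z, y, x] <- n
  }
  list(phi = phi, count = cnt)
}

# per-band histogram accumulation by exhaustive loops
oracle_histograms <- function(vols, masks, n_bands, thickness, radius, levels) {
  hf <- hb <- matrix(0L, n_bands, levels)
  for (i in seq_along(vols)) {
    band <- oracle_bands(masks[[i]], n_bands, thickness)
    r <- oracle_phi(vols[[i]], band, radius)
    d <- dim(vols[[i]])
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      b <- band[z, y, x]
      if (b == 0) next
      lev <- floor(r$phi[z, y, x] / r$count[z, y, x] + 0.5) + 1L
      if (masks[[i]][z, y, x] == 1) hf[b, lev] <- hf[b, lev] + 1L
      else hb[b, lev] <- hb[b, lev] + 1L
    }
  }
  list(fg = hf, bg = hb)
}

# symmetric surface distances by exhaustive pairwise search
oracle_surface_distances <- function(pred, ref, spacing) {
  boundary <- function(m) {
    d <- dim(m)
    idx <- NULL
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (m[z, y, x] != 1) next
      nb <- c(if (z > 1) m[z - 1, y, x] else 0L, if (z < d[1]) m[z + 1, y, x] else 0L,
              if (y > 1) m[z, y - 1, x] else 0L, if (y < d[2]) m[z, y + 1, x] else 0L,
              if (x > 1) m[z, y, x - 1] else 0L, if (x < d[3]) m[z, y, x + 1] else 0L)
      if (any(nb == 0)) idx <- rbind(idx, c(z, y, x))
    }
    idx
  }
  bp <- boundary(pred); br <- boundary(ref)
  one_way <- function(a, b) {
    apply(a, 1, function(v) {
      sqrt(min(((v[1] - b[, 1]) * spacing[1])^2 + ((v[2] - b[, 2]) * spacing[2])^2 +
                 ((v[3] - b[, 3]) * spacing[3])^2))
    })
  }
  sort(c(one_way(bp, br), one_way(br, bp)))
}

# a small random blob mask guaranteed non-empty
random_blob <- function(d, seed) {
  set.seed(seed)
  ctr <- d / 2 + runif(3, -1, 1)
  r <- runif(1, 1.2, max(1.6, min(d) / 2.2))
  z <- slice.index(array(0, d), 1); y <- slice.index(array(0, d), 2)
  x <- slice.index(array(0, d), 3)
  binary_mask(array(
    as.integer((z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2 <= r^2), d))
}

# tiny quantized cohort for the appearance-prior oracle tests: (3, 8, 8)
# volumes on a handful of gray levels with blob masks
toy_cohort <- function(n = 3, d = c(3, 8, 8), levels = 16, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- random_blob(d, seed + i)
    v <- array(sample(0:(levels - 1), prod(d), replace = TRUE), d)
    vol <- grid_volume(array(as.double(v), d))
    attr(vol, "levels") <- levels
    list(volume = vol, mask = m)
  })
}

# small phantom cohort helper for network tests
tiny_cohort <- function(n, grid = c(8, 24, 24), modality = "dw_like", seed = 1) {
  make_cohort(phantom_config(n_subjects = n, grid = grid, modality = modality,
                             seed = seed))
}
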