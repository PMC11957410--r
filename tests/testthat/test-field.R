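# Field builders: plane waves, spherical waves, time evolution

test_that("a single axial wave reproduces sqrt(2) cos(k0 z) exactly", {
  m <- glw_model(0.05, 128, 0, d = 40, n_waves = 1, grid_n = 32)
  w <- data.frame(kx = 0, ky = 0, kz = m$dist$k0, phase = 0)
  class(w) <- c("partial_waves", "data.frame")
  f <- plane_wave_field(m, waves = w)
  z <- (seq_len(32) - 0.5) * m$spacing
  expected <- sqrt(2) * cos(m$dist$k0 * z)
  expect_equal(as.numeric(Re(f$values[1, 1, ])), expected, tolerance = 1e-10)
  expect_equal(as.numeric(Re(f$values[17, 5, ])), expected, tolerance = 1e-10)
})

test_that("normalization gives unit variance of Re S", {
  # isotropic fields self-average in 3-D: per-realization variance is 1
  for (s in 1:4) {
    m <- glw_model(0.05, 0, 0, n_waves = 500, grid_n = 32, seed = s)
    expect_equal(var(as.numeric(Re(plane_wave_field(m)$values))), 1,
                 tolerance = 0.05)
  }
  # strongly aligned fields are effectively one-dimensional, so the box
  # variance fluctuates realization to realization; the unit variance is
  # an ensemble property
  vs <- vapply(1:100, function(s) {
    m <- glw_model(0.05, 128, 0, n_waves = 500, grid_n = 32, seed = s)
    var(as.numeric(Re(plane_wave_field(m)$values)))
  }, numeric(1))
  expect_equal(mean(vs), 1, tolerance = 0.05)

  # oracle: brute-force evaluation of the analytic sum at a few voxels
  m <- glw_model(0.05, 128, 0, n_waves = 500, grid_n = 48, seed = 9)
  f <- plane_wave_field(m)
  w <- sample_wavevectors(m$dist, m$n_waves, seed = m$seed)
  pick <- cbind(c(1, 10, 33), c(5, 20, 48), c(7, 40, 2))
  for (r in seq_len(nrow(pick))) {
    pos <- (pick[r, ] - 0.5) * m$spacing
    s <- sqrt(2 / m$n_waves) * sum(exp(1i *
      (w$kx * pos[1] + w$ky * pos[2] + w$kz * pos[3] + w$phase)))
    expect_equal(f$values[pick[r, 1], pick[r, 2], pick[r, 3]], s,
                 tolerance = 1e-8)
  }
})

test_that("builders are pure functions of (params, seed)", {
  m <- glw_model(0.1, 10, 0.2, n_waves = 200, grid_n = 32, seed = 42)
  f1 <- plane_wave_field(m)
  f2 <- plane_wave_field(m)
  expect_identical(f1$values, f2$values)
  m2 <- m; m2$seed <- 43L
  expect_false(identical(plane_wave_field(m2)$values, f1$values))
})

test_that("spherical waves give radial phase and concentric shells", {
  m <- glw_model(0.02, 1, 0.3, d = 40, n_waves = 1, grid_n = 48, seed = 1)
  # single wave centered exactly at the box center, phase 0
  w <- data.frame(kx = 0, ky = 0, kz = m$dist$k0, phase = 0)
  class(w) <- c("partial_waves", "data.frame")
  f <- spherical_wave_field(m, waves = w, origin_spread = 0)
  ctr <- m$box_edge / 2
  cc <- (seq_len(48) - 0.5) * m$spacing
  for (probe in list(c(4, 10, 20), c(30, 44, 7))) {
    r <- sqrt(sum((cc[probe] - ctr)^2))
    ph_expect <- (m$dist$k0 * r) %% (2 * pi)
    ph_got <- Arg(f$values[probe[1], probe[2], probe[3]]) %% (2 * pi)
    expect_equal(ph_got, ph_expect, tolerance = 1e-8)
  }
  # |S| spherically symmetric when all origins coincide and k equal
  m2 <- glw_model(0, 1, 0.3, d = 40, n_waves = 50, grid_n = 48, seed = 2)
  f2 <- spherical_wave_field(m2, origin_spread = 0)
  a <- abs(f2$values)
  mid <- 24
  expect_equal(a[mid + 8, mid, mid], a[mid, mid + 8, mid], tolerance = 0.02)
  expect_equal(a[mid + 8, mid, mid], a[mid, mid, mid + 8], tolerance = 0.02)

  # onion morphology: angular average of the clipped density alternates
  m3 <- glw_model(0.05, 1, 0.3, d = 40, n_waves = 100, grid_n = 64, seed = 3)
  f3 <- spherical_wave_field(m3, origin_spread = m3$d)
  rho <- clip_to_sld(f3, 0.3)
  cc <- (seq_len(64) - 0.5) * m3$spacing - m3$box_edge / 2
  rr <- sqrt(outer(outer(cc^2, cc^2, "+"), cc^2, "+"))
  shell <- floor(rr / (m3$d / 4))
  prof <- tapply(as.numeric(rho$values), as.numeric(shell), mean)
  prof <- prof[seq_len(12)]   # inner shells, away from box corners
  alternations <- sum(abs(diff(prof > mean(prof))) > 0)
  expect_gte(alternations, 3)
})

test_that("origin spread must be nonnegative", {
  m <- glw_model(0.05, 1, 0.3, grid_n = 32)
  expect_error(spherical_wave_field(m, origin_spread = -1), "origin_spread")
})

test_that("time evolution reduces to the static field at t = 0", {
  m <- glw_model(0.1, 10, 0.2, n_waves = 100, grid_n = 32, seed = 5)
  frames <- evolve_field(m, times = c(0, 0.5, 1), omega0 = 1,
                         sigma_omega = 0.3)
  expect_identical(frames[[1]]$values, plane_wave_field(m)$values)
})

test_that("zero rate dispersion yields a global phase rotation", {
  m <- glw_model(0.1, 10, 0.2, n_waves = 100, grid_n = 32, seed = 6)
  frames <- evolve_field(m, times = c(0, 0.7), omega0 = 2, sigma_omega = 0)
  expect_equal(abs(frames[[2]]$values), abs(frames[[1]]$values),
               tolerance = 1e-10)
  # and the rotation angle is omega0 * t
  ratio <- frames[[2]]$values[5, 5, 5] / frames[[1]]$values[5, 5, 5]
  expect_equal(Arg(ratio) %% (2 * pi), (2 * 0.7) %% (2 * pi),
               tolerance = 1e-8)
})

test_that("variance stays normalized along a dynamic trajectory", {
  # the box spans ~8 correlation lengths per axis, so a single frame's
  # variance carries a few percent of sampling noise; the normalization
  # contract is on the ensemble: average over frames and realizations
  vs <- unlist(lapply(7:10, function(s) {
    m <- glw_model(0.05, 0, 0, n_waves = 500, grid_n = 32, seed = s)
    frames <- evolve_field(m, times = c(0, 1, 2), omega0 = 1,
                           sigma_omega = 0.5)
    vapply(frames, function(f) var(as.numeric(Re(f$values))), numeric(1))
  }))
  expect_equal(mean(vs), 1, tolerance = 0.05)
  # and no frame drifts far from the static statistics
  expect_true(all(abs(vs - 1) < 0.2))
})

test_that("empty or non-increasing time lists are rejected", {
  m <- glw_model(0.1, 10, 0.2, grid_n = 32)
  expect_error(evolve_field(m, times = numeric(0)), "non-empty")
  expect_error(evolve_field(m, times = c(1, 1)), "increasing")
})

test_that("isotropic ensembles scatter isotropically", {
  # gamma -> 0: 3-D intensity at |Q| = k0 has low angular anisotropy
  ratios <- vapply(1:4, function(i) {
    m <- glw_model(0.05, 0, 0.3, n_waves = 2000, grid_n = 48, seed = 100 + i)
    ig <- scattering_intensity(clip_to_sld(plane_wave_field(m)))
    f <- glwave:::fft_freq(48)
    qd <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+")) / m$box_factor
    shell <- abs(qd - 1) < 0.1
    # direction bins: octants by sign pattern
    sx <- outer(outer(sign(f + 0.5), rep(1, 48)), rep(1, 48))
    sy <- outer(outer(rep(1, 48), sign(f + 0.5)), rep(1, 48))
    sz <- outer(outer(rep(1, 48), rep(1, 48)), sign(f + 0.5))
    oct <- (sx > 0) + 2 * (sy > 0) + 4 * (sz > 0)
    means <- tapply(ig$values[shell], oct[shell], mean)
    max(means) / min(means)
  }, numeric(1))
  expect_lt(mean(ratios), 1.3)
})
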