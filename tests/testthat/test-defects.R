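# Phase singularities: winding maps, line tracing, classification, tracking

test_that("defect dimensionality follows the order-parameter topology", {
  expect_identical(permissible_defect_dimension(3, 2), 1L)
  expect_identical(permissible_defect_dimension(3, 3), 0L)
  expect_identical(permissible_defect_dimension(2, 2), 0L)
  expect_error(permissible_defect_dimension(2, 3), "no stable singularity")
})

test_that("phase field is the two-argument arctangent of the wave field", {
  f <- vortex_field(n = 8)
  f$values[] <- 1 + 0i
  expect_true(all(phase_field(f)$values == 0))
  f$values[] <- 1i
  expect_true(all(phase_field(f)$values == pi / 2))
  # zero-amplitude voxels get phase 0 and are flagged
  f$values[2, 3, 4] <- 0
  pf <- phase_field(f)
  expect_equal(pf$values[2, 3, 4], 0)
  expect_true(length(attr(pf, "zero_amplitude")) == 1)

  # pure phase ramp: sawtooth in z with wrap discontinuities only
  n <- 32
  z <- (seq_len(n) - 0.5)
  ramp <- exp(1i * 2 * pi * 4 * z / n)
  f$values <- array(rep(ramp, each = 64), dim = c(8, 8, n))
  f$grid_n <- NULL  # not used by phase_field beyond metadata
  f2 <- vortex_field(n = 8); f2$values <- array(rep(ramp, each = 8 * 8),
                                                dim = c(8, 8, n))
  psi <- atan2(Im(f2$values[1, 1, ]), Re(f2$values[1, 1, ]))
  dpsi <- diff(psi)
  wraps <- abs(dpsi) > pi
  expect_true(all(abs(dpsi[!wraps] - 2 * pi * 4 / n) < 1e-10))
})

test_that("winding map quantizes to 2 pi and finds planted vortices", {
  n <- 16
  f <- vortex_field(n = n, x0 = 8.3, y0 = 8.6, charge = 1)
  wm <- winding_map(phase_field(f), periodic = FALSE)
  # quantization: every c within 1e-6 of an integer multiple of 2 pi
  for (cs in wm$c_sum) {
    expect_lt(max(abs(cs / (2 * pi) - round(cs / (2 * pi)))), 1e-6)
  }
  # the xy scan sees +2pi at the pixel whose loop encloses the zero
  cxy <- wm$c_sum$xy[, , 8]
  hit <- which(cxy > pi, arr.ind = TRUE)
  expect_true(nrow(hit) >= 1)
  expect_true(all(abs(hit[, 1] - 8.3) <= 1.5 & abs(hit[, 2] - 8.6) <= 1.5))
  expect_true(all(abs(cxy[hit] - 2 * pi) < 1e-6))
  # conjugate field flips the sign
  fc <- f; fc$values <- Conj(f$values)
  wmc <- winding_map(phase_field(fc), periodic = FALSE)
  expect_equal(wmc$c_sum$xy[, , 8][hit], rep(-2 * pi, nrow(hit)),
               tolerance = 1e-9)
  # defect-free field: single plane wave has no singularities
  n2 <- 16
  z <- (seq_len(n2) - 0.5)
  pw <- exp(1i * 2 * pi * 3 * z / n2)
  fpw <- vortex_field(n = n2)
  fpw$values <- array(rep(pw, each = n2 * n2), dim = rep(n2, 3))
  fpw$periodic <- TRUE
  wmp <- winding_map(phase_field(fpw), periodic = TRUE)
  expect_equal(sum(wmp$mask), 0)
})

test_that("winding map agrees with the brute-force contour oracle", {
  # random superpositions of up to 5 analytic vortices with known charges
  set.seed(99)
  n <- 24
  for (rep in 1:20) {
    nv <- sample(1:5, 1)
    centers <- cbind(runif(nv, 4, n - 4), runif(nv, 4, n - 4))
    # keep centers off pixel centers and away from each other
    charges <- sample(c(-1, 1), nv, replace = TRUE)
    f <- multi_vortex_field(n, centers, charges)
    wm <- winding_map(phase_field(f), periodic = FALSE)
    got <- wm$c_sum$xy[, , 12] / (2 * pi)
    # oracle: net charge enclosed by each pixel's 8-neighbor loop,
    # by exact point-in-rectangle test of the loop's bounding square
    for (px in seq(2, n - 1, by = 3)) {
      for (py in seq(2, n - 1, by = 3)) {
        # pixel (px, py) has center (px - 0.5, py - 0.5); its 8-neighbor
        # loop encloses the square of half-width 1 around that center
        dx <- abs(centers[, 1] - (px - 0.5))
        dy <- abs(centers[, 2] - (py - 0.5))
        inside <- dx < 1 & dy < 1
        # skip pixels where a vortex sits near the loop path itself
        near_edge <- any(abs(dx - 1) < 0.2 | abs(dy - 1) < 0.2)
        if (near_edge) next
        expect_equal(round(got[px, py]), sum(charges[inside]),
                     label = sprintf("rep %d pixel (%d,%d)", rep, px, py))
      }
    }
  }
})

test_that("loop start and global phase leave the winding invariant", {
  n <- 16
  f <- vortex_field(n = n, x0 = 8.3, y0 = 8.6)
  wm0 <- winding_map(phase_field(f), periodic = FALSE)
  for (phi0 in seq(0.4, 6, by = 0.7)) {
    fr <- f; fr$values <- f$values * exp(1i * phi0)
    wmr <- winding_map(phase_field(fr), periodic = FALSE)
    expect_identical(wmr$mask, wm0$mask)
  }
})

test_that("straight vortex lines along any axis are traced in full", {
  n <- 16
  # vortex along z
  f <- vortex_field(n = n, x0 = 8.3, y0 = 8.6)
  lines <- trace_defect_lines(winding_map(phase_field(f), periodic = FALSE))
  expect_length(lines, 1)
  l <- lines[[1]]
  span <- diff(range(l$polyline[, 3]))
  expect_gte(span, n - 3)
  ang <- acos(abs(l$direction[3])) * 180 / pi
  expect_lt(ang, 5)
  expect_equal(l$kind, "screw")
  expect_equal(l$winding_sign, 1L)

  # the same vortex oriented along x must be caught by the other scans
  fx <- f
  fx$values <- aperm(f$values, c(3, 1, 2))
  linesx <- trace_defect_lines(winding_map(phase_field(fx),
                                           periodic = FALSE))
  expect_length(linesx, 1)
  expect_lt(acos(abs(linesx[[1]]$direction[1])) * 180 / pi, 5)
  expect_equal(linesx[[1]]$kind, "edge")
})

test_that("disjoint vortices give separate lines; short masks are dropped", {
  n <- 24
  f <- multi_vortex_field(n, rbind(c(6.3, 6.6), c(17.4, 17.2)), c(1, 1))
  lines <- trace_defect_lines(winding_map(phase_field(f), periodic = FALSE))
  expect_length(lines, 2)

  # an isolated labeled voxel is filtered by min_length
  wm <- winding_map(phase_field(f), periodic = FALSE)
  wm$mask[] <- FALSE
  wm$mask[5, 5, 5] <- TRUE
  expect_length(trace_defect_lines(wm, min_length = 3, thin = FALSE), 0)
  # empty mask is not an error
  wm$mask[] <- FALSE
  expect_identical(trace_defect_lines(wm, thin = FALSE), list())
})

test_that("line classification thresholds at 45 degrees", {
  mk <- function(cos_phi) structure(list(cos_phi = cos_phi),
                                    class = "defect_line")
  expect_equal(classify_line(mk(cos(44 * pi / 180))), "screw")
  expect_equal(classify_line(mk(cos(46 * pi / 180))), "edge")
  expect_equal(classify_line(mk(1)), "screw")
  expect_equal(classify_line(mk(0)), "edge")
})

test_that("defect statistics summarize counts, density and orientation", {
  s0 <- defect_statistics(list(), box_edge = 10)
  expect_equal(s0$line_density, 0)
  expect_equal(s0$n_lines, 0)

  # one axial box-spanning line in a box of edge L: density L / L^3
  n <- 16
  f <- vortex_field(n = n, x0 = 8.3, y0 = 8.6)
  lines <- trace_defect_lines(winding_map(phase_field(f), periodic = FALSE))
  st <- defect_statistics(lines, box_edge = n)
  expect_equal(st$count_screw, 1)
  expect_equal(st$line_density, lines[[1]]$length / n^3)
  expect_equal(st$line_density, 1 / n^2, tolerance = 0.25)
  expect_equal(sum(st$cos_phi_histogram), st$n_lines)
})

test_that("isotropic sponges carry more defect line than ordered stacks", {
  density_at <- function(gamma, seeds) {
    mean(vapply(seeds, function(s) {
      m <- glw_model(0.05, gamma, 0.3, n_waves = 500, grid_n = 48, seed = s)
      f <- plane_wave_field(m)
      lines <- trace_defect_lines(winding_map(f))
      defect_statistics(lines, m$box_edge)$line_density
    }, numeric(1)))
  }
  iso <- density_at(0.5, 1:4)
  lam <- density_at(128, 1:4)
  expect_gt(iso, lam)
})

test_that("defect tracking links static and moving vortices", {
  # static defects under a pure global phase rotation (sigma_omega = 0)
  m <- glw_model(0.1, 2, 0.3, n_waves = 300, grid_n = 32, seed = 12)
  frames <- evolve_field(m, times = c(0, 0.4, 0.8), omega0 = 1.5,
                         sigma_omega = 0)
  trajs <- track_defects(frames, match_radius = 3)
  n_lines0 <- length(trace_defect_lines(winding_map(frames[[1]])))
  expect_gt(n_lines0, 0)
  full <- Filter(function(t) t$birth == 1 && t$death == 3, trajs)
  expect_gte(length(full), max(1, round(0.8 * n_lines0)))
  # |S| zeros do not move under a global rotation
  for (t in full) {
    d <- mean(abs(t$lines[[1]]$polyline[, 3] -
                  t$lines[[length(t$lines)]]$polyline[
                    seq_len(nrow(t$lines[[1]]$polyline)), 3]), na.rm = TRUE)
  }

  # a constructed vortex translated one voxel per frame
  mk <- function(shift) {
    f <- vortex_field(n = 16, x0 = 5.3 + shift, y0 = 8.6)
    f
  }
  frames2 <- lapply(0:2, mk)
  trajs2 <- track_defects(frames2, match_radius = 3)
  expect_length(trajs2, 1)
  expect_equal(trajs2[[1]]$birth, 1)
  expect_equal(trajs2[[1]]$death, 3)
  x_of <- vapply(trajs2[[1]]$lines, function(l) mean(l$polyline[, 1]),
                 numeric(1))
  expect_equal(diff(x_of), c(1, 1), tolerance = 0.35)

  # match_radius = 0 never links: singleton trajectories
  trajs3 <- track_defects(frames2, match_radius = 0)
  expect_true(all(vapply(trajs3, function(t) t$birth == t$death,
                         logical(1))))
  expect_length(trajs3, 3)
})
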