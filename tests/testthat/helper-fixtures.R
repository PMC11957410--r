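# Shared fixtures. Expensive artifacts (ensemble spectra, the trained
# surrogate) are memoized for the session so several test files can share
# one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# analytic single vortex of charge m at (x0, y0), uniform along z
vortex_field <- function(n = 16, x0 = NULL, y0 = NULL, charge = 1,
                         spacing = 1) {
  if (is.null(x0)) x0 <- (n / 2 + 0.2) * spacing
  if (is.null(y0)) y0 <- (n / 2 + 0.3) * spacing
  cc <- (seq_len(n) - 0.5) * spacing
  zx <- outer(cc - x0, rep(1, n))
  zy <- outer(rep(1, n), cc - y0)
  w <- (zx + 1i * zy)
  if (charge < 0) w <- Conj(w)
  w <- w^abs(charge)
  vals <- array(0 + 0i, dim = c(n, n, n))
  for (iz in seq_len(n)) vals[, , iz] <- w
  structure(
    list(values = vals, spacing = spacing, grid_n = n,
         box_edge = n * spacing, periodic = FALSE,
         model = NULL),
    class = "wave_field"
  )
}

# superposition of several 2-D vortices (as a product of unit-winding
# factors), constant along z
multi_vortex_field <- function(n, centers, charges, spacing = 1) {
  cc <- (seq_len(n) - 0.5) * spacing
  w <- matrix(1 + 0i, n, n)
  for (j in seq_along(charges)) {
    zx <- outer(cc - centers[j, 1], rep(1, n))
    zy <- outer(rep(1, n), cc - centers[j, 2])
    f <- zx + 1i * zy
    if (charges[j] < 0) f <- Conj(f)
    for (m in seq_len(abs(charges[j]))) w <- w * f
  }
  vals <- array(0 + 0i, dim = c(n, n, n))
  for (iz in seq_len(n)) vals[, , iz] <- w
  structure(
    list(values = vals, spacing = spacing, grid_n = n,
         box_edge = n * spacing, periodic = FALSE, model = NULL),
    class = "wave_field"
  )
}

# brute-force continuous winding number of a loop of complex samples
brute_winding <- function(z) {
  ph <- Arg(z)
  d <- diff(c(ph, ph[1]))
  d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
  sum(d) / (2 * pi)
}
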