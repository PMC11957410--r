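new_wave_field <- function(values, model, periodic) {
  structure(
    list(values = values, spacing = model$spacing, grid_n = model$grid_n,
         box_edge = model$box_edge, periodic = periodic, model = model),
    class = "wave_field"
  )
}

#' @export
print.wave_field <- function(x, ...) {
  cat(sprintf("Complex wave field: %d^3 voxels, spacing %.4g, %s\n",
              x$grid_n, x$spacing,
              if (x$periodic) "periodic" else "non-periodic"))
  invisible(x)
}

#' Build a plane-wave superposition field
#'
#' Evaluates \deqn{S(r) = \sqrt{2/n} \sum_n \exp[i(k_n \cdot r + \phi_n)]}
#' at voxel centers \code{(i + 1/2) * spacing}. The \eqn{\sqrt{2/n}}
#' normalization makes the real part of \code{S} a unit-variance field in
#' the large-\code{n} limit, which fixes the meaning of the clipping level
#' in \code{\link{clip_to_sld}}.
#'
#' @param model A \code{\link{glw_model}}.
#' @param waves Optional \code{partial_waves}; defaults to
#'   \code{sample_wavevectors(model$dist, model$n_waves, seed = model$seed)}.
#' @return A \code{"wave_field"}: complex array \code{values} of dimension
#'   \code{grid_n^3} plus grid metadata.
#' @export
plane_wave_field <- function(model, waves = NULL) {
  stopifnot(inherits(model, "glw_model"))
  if (is.null(waves))
    waves <- sample_wavevectors(model$dist, model$n_waves, seed = model$seed)
  vals <- cpp_plane_field(waves$kx, waves$ky, waves$kz, waves$phase,
                          model$grid_n, model$spacing)
  dim(vals) <- rep(model$grid_n, 3)
  new_wave_field(vals, model, periodic = TRUE)
}

#' Build a spherical-wave superposition field
#'
#' Replaces the plane-wave basis by radial phase waves
#' \eqn{\exp[i(k_n |r - c_n| + \phi_n)]} whose origins \eqn{c_n} are
#' normally dispersed around the box center with standard deviation
#' \code{origin_spread}. Clipping the result yields concentric, onion-like
#' multilamellar shells. The default amplitude is constant (a pure phase
#' wave); a \code{1/r} decay is available via \code{amplitude}, but it
#' concentrates contrast at the origins.
#'
#' @param model A \code{\link{glw_model}}.
#' @param waves Optional \code{partial_waves}.
#' @param origin_spread Standard deviation (length units) of the isotropic
#'   normal dispersion of wave origins (>= 0).
#' @param amplitude \code{"unit"} (default) or \code{"inverse_r"}.
#' @return A non-periodic \code{"wave_field"}; origins are attached as
#'   attribute \code{"origins"}.
#' @export
spherical_wave_field <- function(model, waves = NULL, origin_spread = NULL,
                                 amplitude = c("unit", "inverse_r")) {
  stopifnot(inherits(model, "glw_model"))
  amplitude <- match.arg(amplitude)
  if (is.null(origin_spread)) origin_spread <- model$d
  if (origin_spread < 0) stop("'origin_spread' must be >= 0")
  if (is.null(waves))
    waves <- sample_wavevectors(model$dist, model$n_waves, seed = model$seed)
  nw <- nrow(waves)
  center <- model$box_edge / 2
  origins <- local_seed(model$seed + 7919L, {
    matrix(rnorm(3 * nw, mean = center, sd = origin_spread), ncol = 3)
  })
  kmag <- sqrt(waves$kx^2 + waves$ky^2 + waves$kz^2)
  vals <- cpp_spherical_field(kmag, origins[, 1], origins[, 2], origins[, 3],
                              waves$phase, model$grid_n, model$spacing,
                              amplitude == "inverse_r")
  dim(vals) <- rep(model$grid_n, 3)
  fld <- new_wave_field(vals, model, periodic = FALSE)
  attr(fld, "origins") <- origins
  fld
}

#' Time evolution of a wave field
#'
#' Adds a phase \eqn{\omega_n t} to each partial wave, with
#' \eqn{\omega_n \sim N(\omega_0, \sigma_\omega)} (the assumed normal
#' density of oscillation rates), and rebuilds the field at each requested
#' time. The frame at \code{t = 0} is bit-for-bit the static field.
#'
#' @param model A \code{\link{glw_model}}.
#' @param times Strictly increasing numeric vector of sample times.
#' @param omega0 Mean angular rate (rad / time).
#' @param sigma_omega Standard deviation of the angular rate (>= 0).
#' @param waves Optional \code{partial_waves}.
#' @return List of \code{"wave_field"} frames (one per time); the drawn
#'   rates are attached as attribute \code{"omega"} and times as
#'   \code{"times"}.
#' @export
evolve_field <- function(model, times, omega0 = 0, sigma_omega = 0,
                         waves = NULL) {
  stopifnot(inherits(model, "glw_model"))
  if (length(times) == 0) stop("'times' must be a non-empty vector")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (sigma_omega < 0) stop("'sigma_omega' must be >= 0")
  if (is.null(waves))
    waves <- sample_wavevectors(model$dist, model$n_waves, seed = model$seed)
  nw <- nrow(waves)
  omega <- local_seed(model$seed + 104729L, rnorm(nw, omega0, sigma_omega))
  frames <- lapply(times, function(t) {
    w <- waves
    w$phase <- (w$phase + omega * t) %% (2 * pi)
    if (t == 0) w$phase <- waves$phase  # exact zero-time identity
    plane_wave_field(model, waves = w)
  })
  attr(frames, "omega") <- omega
  attr(frames, "times") <- times
  frames
}
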