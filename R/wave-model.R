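#' Anisotropic wave-vector distribution
#'
#' Defines the factorized distribution of wave vectors used to build
#' distorted-lamellar wave fields: the magnitude \eqn{|k|} is normal with
#' mean \code{k0} and standard deviation \code{sigma_k * k0} (truncated to
#' positive values), the azimuth is uniform on \eqn{[0, 2\pi)}, and the
#' cosine of the polar angle follows the Fisher (von Mises--Fisher) density
#' proportional to \eqn{\exp(\Gamma \cos\theta)} about the +z layer normal.
#'
#' \code{gamma} is the orientational order parameter: \code{gamma = 0} gives
#' an isotropic (sponge-like) ensemble, large \code{gamma} a strongly
#' aligned lamellar ensemble. \code{sigma_k} measures the relative spread of
#' inter-layer spacing.
#'
#' @param k0 Mean wavenumber (rad / length); \code{k0 = 2*pi/d} for mean
#'   layer spacing \code{d}.
#' @param sigma_k Relative standard deviation of \eqn{|k|} (dimensionless,
#'   >= 0).
#' @param gamma Fisher concentration (dimensionless, >= 0).
#' @return An object of class \code{"wave_distribution"} with fields
#'   \code{k0}, \code{sigma_k}, \code{gamma} and the polar normalization
#'   constant \code{fisher_norm} (the constant c such that
#'   \eqn{\int_0^\pi c\, e^{\Gamma\cos\theta} \sin\theta\, d\theta = 1}).
#' @export
#' @examples
#' dist <- wave_distribution(k0 = 2 * pi / 40, sigma_k = 0.05, gamma = 128)
#' mean(sample_polar_cosines(dist, 1000, seed = 1))
wave_distribution <- function(k0, sigma_k, gamma) {
  stopifnot(is.numeric(k0), length(k0) == 1L, k0 > 0)
  if (!is.numeric(sigma_k) || length(sigma_k) != 1L || sigma_k < 0)
    stop("'sigma_k' must be a single number >= 0")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("'gamma' must be a single number >= 0")
  # c * int_{-1}^{1} exp(gamma * u) du = 1  =>  c = gamma / (2 sinh gamma)
  fisher_norm <- if (gamma < 1e-12) 0.5 else gamma / (2 * sinh(gamma))
  structure(
    list(k0 = k0, sigma_k = sigma_k, gamma = gamma, fisher_norm = fisher_norm),
    class = "wave_distribution"
  )
}

#' @export
print.wave_distribution <- function(x, ...) {
  cat(sprintf(
    "Wave-vector distribution: k0 = %.5g, sigma_k = %.3g, gamma = %.5g\n",
    x$k0, x$sigma_k, x$gamma))
  invisible(x)
}

#' Sample polar-angle cosines from the Fisher orientation density
#'
#' Draws \eqn{\cos\theta} from the density proportional to
#' \eqn{\exp(\Gamma \cos\theta)} on \eqn{[-1, 1]} using the closed-form
#' inverse CDF \eqn{u = 1 + \log(U + (1-U) e^{-2\Gamma}) / \Gamma}, which is
#' numerically stable at large concentration.
#'
#' @param dist A \code{\link{wave_distribution}}.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer; when given, sampling happens in a local RNG
#'   stream and the caller's RNG state is untouched.
#' @return Numeric vector of \code{n} values in \eqn{[-1, 1]}.
#' @export
sample_polar_cosines <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "wave_distribution"), n >= 1)
  draw <- function() {
    u <- runif(n)
    g <- dist$gamma
    if (g < 1e-12) return(2 * u - 1)
    pmin(1, pmax(-1, 1 + log(u + (1 - u) * exp(-2 * g)) / g))
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Sample a partial-wave set
#'
#' Draws \code{n_waves} wave vectors from an anisotropic distribution
#' together with uniform phase shifts. Magnitudes are normal
#' \eqn{N(k_0, \sigma_k k_0)} truncated to positive values by rejection;
#' the truncation acceptance rate is recorded as an attribute.
#'
#' @param dist A \code{\link{wave_distribution}}.
#' @param n_waves Number of partial waves (>= 1).
#' @param seed Optional integer seed (local RNG stream).
#' @return An object of class \code{"partial_waves"}: a data frame with
#'   columns \code{kx}, \code{ky}, \code{kz}, \code{phase} and attribute
#'   \code{acceptance_rate}.
#' @export
sample_wavevectors <- function(dist, n_waves, seed = NULL) {
  stopifnot(inherits(dist, "wave_distribution"), n_waves >= 1)
  draw <- function() {
    # |k| ~ N(k0, sigma_k * k0), rejected until positive
    kmag <- rnorm(n_waves, dist$k0, dist$sigma_k * dist$k0)
    tries <- n_waves
    while (any(bad <- kmag <= 0)) {
      kmag[bad] <- rnorm(sum(bad), dist$k0, dist$sigma_k * dist$k0)
      tries <- tries + sum(bad)
    }
    u <- sample_polar_cosines(dist, n_waves)
    st <- sqrt(pmax(0, 1 - u^2))
    az <- runif(n_waves, 0, 2 * pi)
    ph <- runif(n_waves, 0, 2 * pi)
    out <- data.frame(
      kx = kmag * st * cos(az),
      ky = kmag * st * sin(az),
      kz = kmag * u,
      phase = ph
    )
    attr(out, "acceptance_rate") <- n_waves / tries
    class(out) <- c("partial_waves", "data.frame")
    out
  }
  if (is.null(seed)) draw() else local_seed(seed, draw())
}

#' Model parameters for a generalized leveled-wave realization
#'
#' Bundles the three structural parameters (\code{sigma_k}, \code{gamma},
#' \code{alpha}) with the discretization of the periodic simulation cell.
#' The cell edge is an integer multiple of the mean spacing \code{d} so
#' that correlation peaks fall on reciprocal-lattice bins.
#'
#' @param sigma_k Relative dispersion of \eqn{|k|}.
#' @param gamma Fisher orientational order parameter (>= 0).
#' @param alpha Membrane volume fraction in \eqn{[0, 0.95]} (the clipping
#'   level applied by \code{\link{clip_to_sld}}).
#' @param d Mean inter-plane spacing (length units, e.g. Angstrom);
#'   \code{k0 = 2*pi/d}.
#' @param n_waves Number of partial waves (default 1000).
#' @param box_factor Cell edge in units of \code{d} (integer >= 4,
#'   default 8).
#' @param grid_n Voxels per axis (>= 32, default 64).
#' @param seed RNG seed owned by the model; all realizations derive from it.
#' @return An object of class \code{"glw_model"}.
#' @export
#' @examples
#' m <- glw_model(sigma_k = 0.05, gamma = 128, alpha = 0.2, grid_n = 64)
#' f <- plane_wave_field(m)
#' var(Re(f$values))   # ~ 1 by construction
glw_model <- function(sigma_k, gamma, alpha, d = 40, n_waves = 1000,
                      box_factor = 8, grid_n = 64, seed = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 0.95)
    stop("'alpha' must lie in [0, 0.95]")
  stopifnot(d > 0, n_waves >= 1)
  box_factor <- as.integer(box_factor)
  if (box_factor < 4) stop("'box_factor' must be an integer >= 4")
  grid_n <- as.integer(grid_n)
  if (grid_n < 32) stop("'grid_n' must be >= 32")
  dist <- wave_distribution(k0 = 2 * pi / d, sigma_k = sigma_k, gamma = gamma)
  box_edge <- box_factor * d
  spacing <- box_edge / grid_n
  if (dist$k0 * spacing > pi)
    stop("grid too coarse: lamellar period under 2 voxels (aliasing)")
  structure(
    list(dist = dist, alpha = alpha, d = d, n_waves = as.integer(n_waves),
         box_factor = box_factor, box_edge = box_edge, grid_n = grid_n,
         spacing = spacing, seed = as.integer(seed)),
    class = "glw_model"
  )
}

#' @export
print.glw_model <- function(x, ...) {
  cat(sprintf(
    paste0("GLW model: sigma_k = %.3g, gamma = %.5g, alpha = %.3g, ",
           "d = %.4g\n  %d waves, box %d x d, grid %d^3, seed %d\n"),
    x$dist$sigma_k, x$dist$gamma, x$alpha, x$d,
    x$n_waves, x$box_factor, x$grid_n, x$seed))
  invisible(x)
}
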