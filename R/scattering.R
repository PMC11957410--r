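#' Clipping threshold for a given membrane volume fraction
#'
#' For a unit-variance Gaussian field, returns the threshold applied to
#' \code{Re S} so that the clipped membrane occupies volume fraction
#' \code{alpha}. Two conventions are supported:
#' \describe{
#'   \item{\code{"onesided"} (default)}{membrane = \{Re S > beta\} with
#'     \code{beta = qnorm(1 - alpha)}. Slabs are centered on the maxima of
#'     the density wave and spaced one period \code{d} apart, giving a
#'     duty-cycle-\code{alpha} pulse train whose m-th harmonic scales as
#'     \eqn{\sin(\pi m \alpha)/m}: even orders are suppressed as
#'     \code{alpha} grows and vanish at \code{alpha = 0.5}.}
#'   \item{\code{"band"}}{membrane = \{|Re S| < beta\} with
#'     \code{beta = qnorm((1 + alpha)/2)}. Sheets sit on the zero crossings,
#'     which are spaced \code{d/2}; the fundamental then appears at
#'     \code{Q d / 2 pi = 2}. Provided for comparison with symmetric
#'     level-set constructions.}
#' }
#'
#' @param alpha Membrane volume fraction in \eqn{[0, 1)}.
#' @param convention \code{"onesided"} or \code{"band"}.
#' @return The threshold beta (standard normal units).
#' @export
#' @examples
#' clip_threshold(0.5, "band")     # 0.6745, the standard-normal quartile
#' clip_threshold(0.3829, "band")  # 0.5000
clip_threshold <- function(alpha, convention = c("onesided", "band")) {
  convention <- match.arg(convention)
  if (!is.numeric(alpha) || any(alpha < 0) || any(alpha >= 1))
    stop("'alpha' must lie in [0, 1)")
  if (convention == "band") qnorm((1 + alpha) / 2) else qnorm(1 - alpha)
}

#' Clip a wave field to a binary scattering-length-density field
#'
#' Applies the leveled-wave construction: the membrane phase is the set of
#' voxels where \code{Re S} exceeds the \code{alpha}-quantile threshold
#' (see \code{\link{clip_threshold}}), so that \code{alpha} is the membrane
#' volume fraction. \code{alpha} is floored at one voxel per period
#' (\code{spacing/d}) so the degenerate zero-volume case \code{alpha = 0}
#' still produces a one-voxel-thick sheet train.
#'
#' @param field A \code{"wave_field"}.
#' @param alpha Membrane volume fraction; defaults to the model's.
#' @param convention Clipping convention, see \code{\link{clip_threshold}}.
#' @return An object of class \code{"sld_field"}: integer array
#'   \code{values} in \{0, 1\}, \code{spacing}, realized
#'   \code{membrane_fraction}, and the applied \code{threshold}.
#' @export
clip_to_sld <- function(field, alpha = NULL,
                        convention = c("onesided", "band")) {
  stopifnot(inherits(field, "wave_field"))
  convention <- match.arg(convention)
  if (is.null(alpha)) alpha <- field$model$alpha
  if (alpha < 0 || alpha >= 1) stop("'alpha' must lie in [0, 1)")
  # floor: thinnest representable membrane is ~one voxel per period
  alpha_min <- field$spacing / field$model$d
  alpha_eff <- max(alpha, alpha_min)
  beta <- clip_threshold(alpha_eff, convention)
  re <- Re(field$values)
  rho <- if (convention == "band") {
    (abs(re) < beta)
  } else {
    (re > beta)
  }
  storage.mode(rho) <- "integer"
  structure(
    list(values = rho, spacing = field$spacing,
         grid_n = field$grid_n, box_edge = field$box_edge,
         membrane_fraction = mean(rho), threshold = beta,
         alpha = alpha, convention = convention),
    class = "sld_field"
  )
}

#' @export
print.sld_field <- function(x, ...) {
  cat(sprintf("SLD field: %d^3 voxels, membrane fraction %.4f (target %.4f)\n",
              x$grid_n, x$membrane_fraction, x$alpha))
  invisible(x)
}

#' Three-dimensional scattering intensity by FFT
#'
#' Subtracts the mean of the density field, applies the unnormalized
#' forward discrete Fourier transform, and returns
#' \eqn{I(Q) = |F(Q)|^2} on the reciprocal grid (spacing
#' \code{2*pi/box_edge} per axis, FFT frequency ordering). Parseval's
#' identity \eqn{\sum |F|^2 = N^3 \sum (\rho - \bar\rho)^2} holds under
#' this convention.
#'
#' @param x An \code{"sld_field"}, a \code{"wave_field"} (its real part is
#'   used), or a numeric 3-d array.
#' @return An object of class \code{"intensity_grid"}.
#' @export
scattering_intensity <- function(x) {
  if (inherits(x, "sld_field")) {
    arr <- x$values; spacing <- x$spacing; box <- x$box_edge
  } else if (inherits(x, "wave_field")) {
    arr <- Re(x$values); spacing <- x$spacing; box <- x$box_edge
  } else if (is.array(x) && length(dim(x)) == 3) {
    arr <- x; spacing <- 1; box <- dim(x)[1]
  } else stop("'x' must be an sld_field, wave_field or 3-d array")
  dm <- dim(arr)
  if (length(unique(dm)) != 1) stop("grid must be cubic")
  arr <- arr - mean(arr)
  f <- fft(arr)
  structure(
    list(values = Re(f * Conj(f)), grid_n = dm[1],
         box_edge = box, dq = 2 * pi / box),
    class = "intensity_grid"
  )
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("Intensity grid: %d^3 reciprocal voxels, dq = %.5g\n",
              x$grid_n, x$dq))
  invisible(x)
}

# FFT frequency indices 0, 1, ..., N/2-1, -N/2, ..., -1
fft_freq <- function(n) {
  f <- seq_len(n) - 1L
  f[f >= n / 2] <- f[f >= n / 2] - n
  f
}

#' Radially average a 3-D intensity grid to a 1-D spectrum
#'
#' Bins reciprocal voxels by the dimensionless magnitude
#' \eqn{q = |Q| d / 2\pi} and averages the intensity in each bin. The
#' default bin width is one reciprocal-lattice spacing,
#' \code{d / box_edge}. The \code{Q = 0} voxel is excluded; empty bins are
#' dropped. Intensities are reported per voxel, scaled by \code{1/N^3}.
#'
#' @param ig An \code{"intensity_grid"}.
#' @param d Mean spacing used to non-dimensionalize \code{Q} (> 0).
#' @param bin_width Bin width on the \eqn{Qd/2\pi} axis.
#' @param q_max Upper limit of binning (default: half the grid Nyquist
#'   sphere, \code{N/2 * d/box_edge}).
#' @return A \code{"glw_spectrum"}: data frame with columns \code{q},
#'   \code{intensity}, \code{n_contrib}.
#' @export
radial_average <- function(ig, d, bin_width = NULL, q_max = NULL) {
  stopifnot(inherits(ig, "intensity_grid"), d > 0)
  n <- ig$grid_n
  dqd <- d / ig$box_edge                  # one reciprocal-lattice spacing
  if (is.null(bin_width)) bin_width <- dqd
  if (is.null(q_max)) q_max <- (n / 2) * dqd
  f <- fft_freq(n)
  f2 <- f^2
  # |Q| d / 2pi = |f| * d / box_edge
  qd <- sqrt(outer(outer(f2, f2, "+"), f2, "+")) * dqd
  keep <- qd > 0 & qd <= q_max
  # bins centered on multiples of bin_width, so lattice peaks sit on
  # bin centers
  bins <- round(qd[keep] / bin_width)
  ivals <- ig$values[keep] / n^3
  isum <- tapply(ivals, bins, sum)
  cnt <- tapply(ivals, bins, length)
  bidx <- as.numeric(names(isum))
  out <- data.frame(
    q = bidx * bin_width,
    intensity = as.numeric(isum / cnt),
    n_contrib = as.integer(cnt)
  )
  out <- out[order(out$q), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("glw_spectrum", "data.frame"),
            bin_width = bin_width, d = d)
}

#' Ensemble-averaged scattering spectrum of a GLW model
#'
#' Builds \code{n_real} independent field realizations (seeds derived from
#' the model seed by unit increments), clips each to an SLD field, computes
#' intensities, radially averages, and returns the mean spectrum with
#' standard-error uncertainties.
#'
#' @param model A \code{\link{glw_model}}.
#' @param n_real Number of independent realizations (>= 1).
#' @param convention Clipping convention, see \code{\link{clip_threshold}}.
#' @param bin_width Passed to \code{\link{radial_average}}.
#' @return A \code{"glw_spectrum"} with an extra \code{uncertainty} column
#'   (standard error of the bin mean across realizations; \code{NA} when
#'   \code{n_real = 1}).
#' @export
#' @examples
#' \donttest{
#' m <- glw_model(0.05, 128, 0, grid_n = 64, seed = 3)
#' s <- ensemble_spectrum(m, n_real = 2)
#' find_peaks(s)$q   # close to 1, 2, 3
#' }
ensemble_spectrum <- function(model, n_real = 8,
                              convention = c("onesided", "band"),
                              bin_width = NULL) {
  stopifnot(inherits(model, "glw_model"), n_real >= 1)
  convention <- match.arg(convention)
  specs <- lapply(seq_len(n_real) - 1L, function(i) {
    m <- model
    m$seed <- model$seed + i
    fld <- plane_wave_field(m)
    rho <- clip_to_sld(fld, convention = convention)
    radial_average(scattering_intensity(rho), d = model$d,
                   bin_width = bin_width)
  })
  q <- specs[[1]]$q
  imat <- vapply(specs, function(s) s$intensity, numeric(length(q)))
  imat <- matrix(imat, nrow = length(q))
  out <- data.frame(
    q = q,
    intensity = rowMeans(imat),
    uncertainty = if (n_real > 1) apply(imat, 1, sd) / sqrt(n_real)
                  else NA_real_,
    n_contrib = specs[[1]]$n_contrib
  )
  structure(out, class = c("glw_spectrum", "data.frame"),
            bin_width = attr(specs[[1]], "bin_width"), d = model$d,
            n_real = n_real)
}

#' Locate correlation peaks in a 1-D spectrum
#'
#' Finds interior local maxima of (optionally smoothed) intensity and
#' reports their position, height and prominence (height above the higher
#' of the two flanking minima). Used for peak counting, first-peak
#' location, and FWHM measurements.
#'
#' Correlation peaks span decades in height, so counting them is done on
#' the log scale: with \code{log = TRUE} the prominence is measured in
#' log10 units (a prominence of \code{log10(3)} means the peak rises a
#' factor 3 above its surrounding baseline).
#'
#' @param spec A \code{"glw_spectrum"} or any data frame with \code{q} and
#'   \code{intensity} columns.
#' @param q_range Restrict the search window (length-2 numeric).
#' @param smooth Half-width (in bins) of a running-mean smoother; 0 = none.
#' @param min_prominence_frac Discard peaks with prominence below this
#'   fraction of the largest prominence.
#' @param log Detect on log10 intensity (heights and prominences are then
#'   in log10 units).
#' @param min_prominence Absolute prominence floor (applied after the
#'   log transform when \code{log = TRUE}); default none.
#' @return Data frame with columns \code{q}, \code{height},
#'   \code{prominence}, ordered by \code{q}.
#' @export
find_peaks <- function(spec, q_range = NULL, smooth = 0,
                       min_prominence_frac = 0.05, log = FALSE,
                       min_prominence = 0) {
  q <- spec$q
  y <- spec$intensity
  if (!is.null(q_range)) {
    keep <- q >= q_range[1] & q <= q_range[2]
    q <- q[keep]; y <- y[keep]
  }
  if (log) y <- log10(pmax(y, .Machine$double.xmin))
  n <- length(y)
  if (n < 3) return(data.frame(q = numeric(0), height = numeric(0),
                               prominence = numeric(0)))
  if (smooth > 0) {
    k <- 2 * smooth + 1
    y_raw <- y
    y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    # running mean leaves NAs at the ends; fall back to raw values there
    y[is.na(y)] <- y_raw[is.na(y)]
  }
  im <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(im)) return(data.frame(q = numeric(0), height = numeric(0),
                                     prominence = numeric(0)))
  prom <- vapply(im, function(i) {
    lmin <- min(y[1:i]); rmin <- min(y[i:n])
    y[i] - max(lmin, rmin)
  }, numeric(1))
  out <- data.frame(q = q[im], height = y[im], prominence = prom)
  out <- out[out$prominence >= min_prominence_frac * max(prom) &
             out$prominence >= min_prominence, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count correlation peaks near integer positions
#'
#' Detects local maxima of the log10 spectrum within \code{q_max} whose
#' prominence exceeds a factor-\code{baseline_factor} rise over the
#' surrounding baseline, and reports those together with their distance
#' to the nearest integer \eqn{Qd/2\pi}.
#'
#' @param spec A spectrum data frame (\code{q}, \code{intensity}).
#' @param q_max Counting window upper limit (default 3.5).
#' @param baseline_factor Required peak-to-baseline intensity ratio
#'   (default 2).
#' @return Data frame \code{q}, \code{height}, \code{prominence},
#'   \code{nearest_order}, \code{offset_bins} (distance to the nearest
#'   integer in bins).
#' @export
correlation_peaks <- function(spec, q_max = 3.5, baseline_factor = 2) {
  pk <- find_peaks(spec, q_range = c(0.4, q_max), log = TRUE,
                   min_prominence_frac = 0,
                   min_prominence = log10(baseline_factor))
  if (!nrow(pk)) {
    pk$nearest_order <- integer(0); pk$offset_bins <- numeric(0)
    return(pk)
  }
  bw <- attr(spec, "bin_width") %||% min(diff(spec$q))
  pk$nearest_order <- as.integer(round(pk$q))
  pk$offset_bins <- abs(pk$q - pk$nearest_order) / bw
  pk
}

#' Full width at half maximum of the peak nearest a position
#'
#' Linear interpolation of the half-height crossings on either flank of the
#' local maximum closest to \code{q0}.
#'
#' @param spec Spectrum data frame (\code{q}, \code{intensity}).
#' @param q0 Approximate peak position.
#' @return FWHM on the \code{q} axis (NA when a flank never drops to half).
#' @export
peak_fwhm <- function(spec, q0 = 1) {
  q <- spec$q; y <- spec$intensity
  pk <- find_peaks(spec)
  if (!nrow(pk)) return(NA_real_)
  i <- which.min(abs(pk$q - q0))
  ipk <- which.min(abs(q - pk$q[i]))
  half <- y[ipk] / 2
  # walk left
  l <- ipk
  while (l > 1 && y[l] > half) l <- l - 1
  if (y[l] > half) return(NA_real_)
  ql <- q[l] + (q[l + 1] - q[l]) * (half - y[l]) / (y[l + 1] - y[l])
  r <- ipk
  n <- length(y)
  while (r < n && y[r] > half) r <- r + 1
  if (y[r] > half) return(NA_real_)
  qr <- q[r - 1] + (q[r] - q[r - 1]) * (y[r - 1] - half) / (y[r - 1] - y[r])
  qr - ql
}
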