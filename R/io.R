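#' Read a reduced 1-D scattering curve
#'
#' Parses the common reduced-SANS text dialect: 2 or 3 numeric columns
#' (\code{Q} in 1/Angstrom, intensity, optional uncertainty), whitespace
#' or comma separated, with \code{#}-prefixed comment lines and blank
#' lines skipped.
#'
#' @param path File path.
#' @return An \code{"experiment_spectrum"}: data frame with columns
#'   \code{q}, \code{intensity} and (when present) \code{uncertainty};
#'   header comments are kept in attribute \code{"header"}.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  header <- raw[grepl("^\\s*#", raw)]
  body <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (!length(body)) stop("no data rows in ", path)
  sep_comma <- grepl(",", body[1])
  fields <- strsplit(trimws(body), if (sep_comma) "\\s*,\\s*" else "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1)
    stop("inconsistent column counts in ", path)
  if (ncols < 2) stop("need at least 2 columns (q, intensity)")
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE))
  if (anyNA(vals)) stop("non-numeric payload in ", path)
  out <- data.frame(q = vals[, 1], intensity = vals[, 2])
  if (ncols >= 3) out$uncertainty <- vals[, 3]
  if (any(diff(out$q) <= 0)) stop("non-monotone q values in ", path)
  if (any(out$q <= 0)) stop("q values must be positive in ", path)
  structure(out, class = c("experiment_spectrum", "data.frame"),
            header = header)
}

#' Write a spectrum as 3-column ASCII
#'
#' Writes \code{q}, intensity and uncertainty (zero when absent) with
#' \code{#}-prefixed header lines naming the columns and any supplied
#' parameters.
#'
#' @param spec Data frame with \code{q}, \code{intensity}, optional
#'   \code{uncertainty}.
#' @param path Output path.
#' @param comments Optional character vector of extra header lines.
#' @export
write_spectrum <- function(spec, path, comments = character(0)) {
  un <- spec$uncertainty
  if (is.null(un)) un <- rep(0, nrow(spec))
  un[!is.finite(un)] <- 0
  hdr <- c("# q intensity uncertainty", paste0("# ", comments))
  hdr <- hdr[nzchar(gsub("^#\\s*", "", hdr)) | hdr == "# q intensity uncertainty"]
  body <- sprintf("%.10g %.10g %.10g", spec$q, spec$intensity, un)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a synthetic reduced scattering experiment
#'
#' Emulates a reduced SANS curve from the GLW/KAN framework:
#' \eqn{I(Q) = A \hat I(Qd/2\pi) + B} with multiplicative Gaussian noise
#' at a stated relative level. The generating truth is attached so
#' parameter-recovery studies can score fits.
#'
#' @param sigma_k,gamma,alpha True structural parameters.
#' @param d True spacing (Angstrom).
#' @param q Absolute Q grid (1/Angstrom), strictly increasing; may be
#'   non-uniform.
#' @param scale Multiplicative calibration A (default 1).
#' @param background Additive flat background B (default 0).
#' @param noise Relative Gaussian noise level (>= 0, default 0.05).
#' @param source Either a trained \code{\link{kan_surrogate}} or
#'   \code{"simulator"} to use \code{\link{ensemble_spectrum}} directly
#'   (intensities interpolated onto \code{q} from the simulated bins).
#' @param n_real,grid_n,n_waves Simulator settings (used when
#'   \code{source = "simulator"}).
#' @param seed RNG seed for the noise (and simulator).
#' @return An \code{"experiment_spectrum"} with attribute \code{"truth"}
#'   (list of the generating parameters).
#' @export
generate_synthetic_experiment <- function(sigma_k, gamma, alpha, d, q,
                                          scale = 1, background = 0,
                                          noise = 0.05,
                                          source = "simulator",
                                          n_real = 4, grid_n = 64,
                                          n_waves = 1000, seed = 1) {
  if (noise < 0) stop("'noise' must be >= 0")
  if (any(diff(q) <= 0)) stop("'q' must be strictly increasing")
  qd <- q * d / (2 * pi)
  if (inherits(source, "kan_surrogate")) {
    ihat <- kan_forward(source, sigma_k, gamma, alpha, qd)
  } else {
    m <- glw_model(sigma_k, gamma, alpha, d = d, n_waves = n_waves,
                   grid_n = grid_n, seed = seed + 17L)
    sp <- ensemble_spectrum(m, n_real = n_real)
    if (min(qd) < min(sp$q) || max(qd) > max(sp$q))
      stop("q window empty or outside the simulated range after d-scaling")
    ihat <- exp(stats::approx(sp$q, log(pmax(sp$intensity, 1e-300)),
                              xout = qd)$y)
  }
  iclean <- scale * ihat + background
  iobs <- local_seed(seed, iclean * (1 + noise * rnorm(length(q))))
  out <- data.frame(q = q, intensity = iobs,
                    uncertainty = noise * abs(iclean))
  structure(out, class = c("experiment_spectrum", "data.frame"),
            truth = list(sigma_k = sigma_k, gamma = gamma, alpha = alpha,
                         d = d, scale = scale, background = background,
                         noise = noise, seed = seed))
}

#' Save / load package objects
#'
#' Fields, SLD fields, winding maps, surrogates and libraries are saved
#' with \code{saveRDS}; spectra use the ASCII writer and configs JSON.
#'
#' @param x Object to save.
#' @param path Destination path.
#' @export
save_object <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readRDS(path)
}

run_config_keys <- c(
  "sigma_k", "gamma", "alpha", "d", "n_waves", "box_factor", "grid_n",
  "seed", "n_real", "convention", "origin_spread", "amplitude",
  "omega0", "sigma_omega", "times", "n_samples", "epochs", "lr",
  "patience", "grid_size", "q_window", "min_length", "match_radius",
  "noise", "scale", "background", "out_dir", "verbosity"
)

#' Read and validate a JSON run configuration
#'
#' Accepts only known keys (see \code{glwave:::run_config_keys});
#' unknown keys are rejected so typos fail loudly. The configuration
#' round-trips unchanged through \code{\link{write_run_config}}.
#'
#' @param path JSON file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @param cfg Named list of configuration values.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export defect lines as CSV
#'
#' One row per polyline vertex: \code{line_id}, \code{vertex_index},
#' \code{x}, \code{y}, \code{z}, \code{kind}, \code{winding_sign}.
#'
#' @param lines List of \code{"defect_line"} objects.
#' @param path Output CSV path.
#' @export
write_defect_lines <- function(lines, path) {
  rows <- lapply(seq_along(lines), function(i) {
    l <- lines[[i]]
    data.frame(line_id = i, vertex_index = seq_len(nrow(l$polyline)),
               x = l$polyline[, 1], y = l$polyline[, 2],
               z = l$polyline[, 3], kind = l$kind,
               winding_sign = l$winding_sign)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line_id = integer(0), vertex_index = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               kind = character(0), winding_sign = integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
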