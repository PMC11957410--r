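#' Permissible defect dimensionality
#'
#' De Gennes' topological argument for ordered media: in a system of
#' spatial dimension \code{d_space} whose order parameter has
#' \code{n_components} components, the stable singularities have dimension
#' \eqn{\delta = d - n}. For the complex wave field (two components: real
#' and imaginary parts) in three dimensions this gives \eqn{\delta = 1}:
#' line defects.
#'
#' @param d_space Spatial dimension (>= 1).
#' @param n_components Number of order-parameter components (>= 1).
#' @return Integer \eqn{\delta >= 0}.
#' @export
#' @examples
#' permissible_defect_dimension(3, 2)  # 1: line defects
#' permissible_defect_dimension(3, 3)  # 0: point defects
permissible_defect_dimension <- function(d_space, n_components) {
  stopifnot(d_space >= 1, n_components >= 1)
  delta <- as.integer(d_space) - as.integer(n_components)
  if (delta < 0)
    stop("no stable singularity of this type (d_space < n_components)")
  delta
}

#' Argument (phase) field of a complex wave field
#'
#' Computes \eqn{\Psi(r) = \mathrm{atan2}(\mathrm{Im}\, S, \mathrm{Re}\, S)}
#' in \eqn{(-\pi, \pi]}. Voxels with exactly zero amplitude get phase 0 and
#' are flagged in the attribute \code{"zero_amplitude"}.
#'
#' @param field A \code{"wave_field"}.
#' @return A \code{"phase_field"}: numeric array of angles plus grid
#'   metadata.
#' @export
phase_field <- function(field) {
  stopifnot(inherits(field, "wave_field"))
  psi <- atan2(Im(field$values), Re(field$values))
  zero <- field$values == 0
  psi[zero] <- 0
  structure(
    list(values = psi, spacing = field$spacing, grid_n = field$grid_n,
         box_edge = field$box_edge, periodic = field$periodic),
    class = "phase_field", zero_amplitude = which(zero)
  )
}

#' Winding-number map of a phase field
#'
#' For every pixel of every 2-D slice, in all three axis orientations,
#' accumulates the wrapped phase differences around the closed
#' counterclockwise loop through the eight neighboring pixels. Each
#' difference is mapped to \eqn{(-\pi, \pi]}, so the sum \code{c} is an
#' exact integer multiple of \eqn{2\pi}; pixels with nonzero winding in at
#' least one orientation form the defect mask.
#'
#' @param psi A \code{"phase_field"} (or a \code{"wave_field"}, converted
#'   automatically).
#' @param periodic Wrap loops across slice boundaries; defaults to the
#'   field's periodicity. When \code{FALSE}, boundary pixels are unlabeled.
#' @return A \code{"winding_map"}: list with \code{c_sum} (3-element list
#'   of cumulative-phase arrays for the yz, zx and xy loop orientations),
#'   \code{winding} (integer array, the dominant \code{c/2pi} over
#'   orientations), \code{mask} (logical array, union over orientations)
#'   and grid metadata.
#' @export
winding_map <- function(psi, periodic = NULL) {
  if (inherits(psi, "wave_field")) psi <- phase_field(psi)
  stopifnot(inherits(psi, "phase_field"))
  if (is.null(periodic)) periodic <- isTRUE(psi$periodic)
  n <- psi$grid_n
  cs <- lapply(0:2, function(ax) {
    v <- cpp_winding(as.numeric(psi$values), n, ax, periodic)
    dim(v) <- rep(n, 3)
    v
  })
  names(cs) <- c("yz", "zx", "xy")
  wind <- lapply(cs, function(v) as.integer(round(v / (2 * pi))))
  mask <- (wind[[1]] != 0L) | (wind[[2]] != 0L) | (wind[[3]] != 0L)
  dim(mask) <- rep(n, 3)
  # dominant winding: the orientation value of largest magnitude
  wmag <- pmax(abs(wind[[1]]), abs(wind[[2]]), abs(wind[[3]]))
  wdom <- wind[[1]]
  wdom[abs(wind[[2]]) == wmag & wdom == 0L] <-
    wind[[2]][abs(wind[[2]]) == wmag & wdom == 0L]
  wdom[abs(wind[[3]]) == wmag & wdom == 0L] <-
    wind[[3]][abs(wind[[3]]) == wmag & wdom == 0L]
  dim(wdom) <- rep(n, 3)
  structure(
    list(c_sum = cs, winding = wdom, mask = mask, grid_n = n,
         spacing = psi$spacing, box_edge = psi$box_edge,
         periodic = periodic),
    class = "winding_map"
  )
}

#' @export
print.winding_map <- function(x, ...) {
  cat(sprintf("Winding map: %d^3 voxels, %d labeled (%.3f%%)\n",
              x$grid_n, sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

# 26-neighbor offsets, fixed deterministic order
neighbor_offsets_26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

#' Trace defect lines from a winding map
#'
#' Reduces the labeled-voxel mask to polylines: voxels are nodes of the
#' 26-connectivity graph; each line is grown by a deterministic greedy walk
#' (depth-first along unvisited neighbors, preferring the continuation
#' closest to the current heading) starting from endpoint voxels (fewest
#' unvisited neighbors first). Junction voxels terminate a walk once
#' visited, so branches become separate lines. Lines shorter than
#' \code{min_length} voxels are dropped.
#'
#' @param wm A \code{"winding_map"} (or a \code{"wave_field"}, converted).
#' @param min_length Minimum number of polyline vertices to keep
#'   (default 3).
#' @param thin Collapse each in-slice cluster of labeled pixels to its
#'   centroid pixel before tracing (default TRUE). The 8-neighbor loop
#'   flags every pixel whose loop encloses a zero, so raw masks are
#'   2--3 pixels wide; thinning recovers one-voxel-wide lines whose
#'   end-to-end directions are meaningful.
#' @return List of \code{"defect_line"} objects; each has \code{polyline}
#'   (matrix of voxel-center coordinates), \code{length} (path length),
#'   \code{direction} (unit end-to-end vector), \code{cos_phi}
#'   (|z component|), \code{winding_sign}, and \code{kind}
#'   (\code{"screw"} or \code{"edge"}, see \code{\link{classify_line}}).
#' @export
trace_defect_lines <- function(wm, min_length = 3, thin = TRUE) {
  if (inherits(wm, "wave_field")) wm <- winding_map(wm)
  stopifnot(inherits(wm, "winding_map"))
  n <- wm$grid_n
  if (thin) {
    tm <- cpp_thin_mask(as.numeric(wm$c_sum$yz), as.numeric(wm$c_sum$zx),
                        as.numeric(wm$c_sum$xy), n)
    idx <- which(tm)
  } else {
    idx <- which(wm$mask)
  }
  if (!length(idx)) return(list())
  lines <- cpp_trace_paths(as.integer(idx), n, as.integer(min_length))

  spacing <- wm$spacing
  lapply(lines, function(path) {
    coords <- arrayInd(path, rep(n, 3))
    pl <- (coords - 0.5) * spacing
    seglen <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                            pl[-nrow(pl), , drop = FALSE])^2))
    v <- pl[nrow(pl), ] - pl[1, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) {
      # degenerate end-to-end direction: use the mean segment direction
      segs <- pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE]
      v <- colMeans(segs / pmax(sqrt(rowSums(segs^2)), 1e-12))
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) v <- c(0, 0, 1) else v <- v / nv
    } else v <- v / nv
    wsign <- wm$winding[path]
    wsign <- wsign[wsign != 0]
    s <- if (length(wsign)) {
      tab <- table(wsign)
      as.integer(names(tab)[which.max(tab)])
    } else 0L
    ln <- structure(
      list(polyline = pl, length = sum(seglen), direction = v,
           cos_phi = abs(v[3]), winding_sign = s),
      class = "defect_line"
    )
    ln$kind <- classify_line(ln)
    ln
  })
}

#' Classify a defect line as screw or edge
#'
#' A line within 45 degrees of the mean layer normal (the z axis), i.e.
#' \eqn{|\cos\Phi| \ge \sqrt{2}/2}, is a screw dislocation; otherwise it is
#' an edge dislocation.
#'
#' @param line A \code{"defect_line"}.
#' @return \code{"screw"} or \code{"edge"}.
#' @export
classify_line <- function(line) {
  stopifnot(inherits(line, "defect_line"))
  if (line$cos_phi >= sqrt(2) / 2) "screw" else "edge"
}

#' Summary statistics of a set of defect lines
#'
#' @param lines List of \code{"defect_line"} objects (one field's worth).
#' @param box_edge Simulation cell edge length (same units as the
#'   polylines).
#' @return A \code{"defect_statistics"} list: \code{line_density} (total
#'   length / volume), \code{count_screw}, \code{count_edge},
#'   \code{cos_phi_histogram} (counts in 10 uniform |cos Phi| bins) and
#'   \code{n_lines}.
#' @export
defect_statistics <- function(lines, box_edge) {
  stopifnot(box_edge > 0)
  kinds <- vapply(lines, function(l) l$kind, character(1))
  total <- sum(vapply(lines, function(l) l$length, numeric(1)))
  cp <- vapply(lines, function(l) l$cos_phi, numeric(1))
  h <- hist(cp, breaks = seq(0, 1, by = 0.1), plot = FALSE,
            include.lowest = TRUE)
  structure(
    list(line_density = total / box_edge^3,
         count_screw = sum(kinds == "screw"),
         count_edge = sum(kinds == "edge"),
         cos_phi_histogram = setNames(h$counts, paste0(
           "[", format(h$breaks[-11], digits = 2), ",",
           format(h$breaks[-1], digits = 2), "]")),
         n_lines = length(lines)),
    class = "defect_statistics"
  )
}

#' @export
print.defect_statistics <- function(x, ...) {
  cat(sprintf(
    "Defect lines: %d (%d screw, %d edge), line density %.4g / vol\n",
    x$n_lines, x$count_screw, x$count_edge, x$line_density))
  invisible(x)
}

#' @importFrom graphics hist
NULL

#' Track defect lines across time frames
#'
#' Detects defect lines in every frame and links them between consecutive
#' frames by greedy minimal mean closest-point distance, accepting a link
#' only below \code{match_radius}. Unmatched lines open new trajectories
#' or close existing ones.
#'
#' @param frames List of \code{"wave_field"} frames (from
#'   \code{\link{evolve_field}}).
#' @param min_length Passed to \code{\link{trace_defect_lines}}.
#' @param match_radius Maximum mean closest-point distance (in voxel
#'   units) for linking lines across frames; default 3.
#' @return List of trajectories; each has \code{birth}, \code{death}
#'   (frame indices) and \code{lines} (the per-frame
#'   \code{"defect_line"} snapshots).
#' @export
track_defects <- function(frames, min_length = 3, match_radius = 3) {
  if (length(frames) < 2) stop("need at least 2 frames")
  gn <- vapply(frames, function(f) f$grid_n, numeric(1))
  if (length(unique(gn)) != 1) stop("frames must share one grid")
  spacing <- frames[[1]]$spacing
  per_frame <- lapply(frames, function(f)
    trace_defect_lines(winding_map(f), min_length = min_length))

  # polylines subsampled to at most 20 vertices for the distance test;
  # per-line geometry is precomputed once per frame
  prep_line <- function(l) {
    p <- l$polyline
    p <- p[unique(round(seq(1, nrow(p), length.out = 20))), , drop = FALSE]
    ctr <- colMeans(l$polyline)
    list(p = p, p2 = rowSums(p^2), ctr = ctr,
         rad = max(sqrt(rowSums(sweep(l$polyline, 2, ctr)^2))))
  }
  line_dist <- function(a, b) {
    # symmetrized mean closest-point distance, in voxel units
    cross <- outer(a$p2, rep(1, nrow(b$p))) +
      outer(rep(1, nrow(a$p)), b$p2) - 2 * a$p %*% t(b$p)
    cross[cross < 0] <- 0
    rmin <- cross[cbind(seq_len(nrow(cross)), max.col(-cross))]
    tc <- t(cross)
    cmin <- tc[cbind(seq_len(nrow(tc)), max.col(-tc))]
    (mean(sqrt(rmin)) + mean(sqrt(cmin))) / 2 / spacing
  }

  trajs <- lapply(per_frame[[1]], function(l)
    list(birth = 1L, death = 1L, lines = list(l)))
  active <- seq_along(trajs)
  for (f in seq_along(per_frame)[-1]) {
    cur <- per_frame[[f]]
    matched_cur <- logical(length(cur))
    still <- integer(0)
    if (length(active) && length(cur)) {
      prev <- lapply(active, function(ti)
        trajs[[ti]]$lines[[length(trajs[[ti]]$lines)]])
      pp <- lapply(prev, prep_line)
      cp <- lapply(cur, prep_line)
      pc <- t(vapply(pp, `[[`, numeric(3), "ctr"))
      pr <- vapply(pp, `[[`, numeric(1), "rad")
      cc <- t(vapply(cp, `[[`, numeric(3), "ctr"))
      cr <- vapply(cp, `[[`, numeric(1), "rad")
      pair_i <- integer(0); pair_j <- integer(0); pair_d <- numeric(0)
      for (i in seq_along(active)) {
        # bounding-sphere prefilter
        lb <- (sqrt(colSums((t(cc) - pc[i, ])^2)) - pr[i] - cr) / spacing
        for (j in which(lb <= match_radius)) {
          d <- line_dist(pp[[i]], cp[[j]])
          if (d < match_radius) {
            pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
            pair_d <- c(pair_d, d)
          }
        }
      }
      # greedy matching: accept pairs in increasing distance order
      used_i <- logical(length(active)); used_j <- logical(length(cur))
      for (k in order(pair_d)) {
        i <- pair_i[k]; j <- pair_j[k]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        ti <- active[i]
        trajs[[ti]]$lines <- c(trajs[[ti]]$lines, list(cur[[j]]))
        trajs[[ti]]$death <- f
        matched_cur[j] <- TRUE
        still <- c(still, ti)
      }
    }
    for (j in which(!matched_cur)) {
      trajs[[length(trajs) + 1]] <- list(birth = f, death = f,
                                         lines = list(cur[[j]]))
      still <- c(still, length(trajs))
    }
    active <- still
  }
  trajs
}
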