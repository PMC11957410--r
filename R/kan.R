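# ---- B-spline edge machinery -------------------------------------------
#
# Every edge of the network carries a learnable univariate function
#   f(x) = sum_j c_j B_j(x) + w * silu(x)
# where B_j are cubic B-splines on a uniform knot grid over the edge
# domain and silu(x) = x / (1 + exp(-x)) is a fixed smooth residual basis
# that keeps gradients alive early in training. Inputs are clamped to the
# domain (documented contract; normalized inputs live in [-1, 1] and
# hidden activations in a wider interval by construction).

kan_knots <- function(domain, grid_size, degree = 3) {
  h <- (domain[2] - domain[1]) / grid_size
  seq(domain[1] - degree * h, domain[2] + degree * h,
      length.out = grid_size + 1 + 2 * degree)
}

kan_basis <- function(x, knots, degree = 3, deriv = 0) {
  # inputs are clamped upstream; outer.ok guards the exact-boundary case
  splines::splineDesign(knots, x, ord = degree + 1,
                        derivs = deriv, outer.ok = TRUE)
}

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

# One KAN layer: w_in inputs -> w_out outputs, each output node summing
# its incoming edge functions. Parameters: coef[[i]] is nb x w_out (spline
# coefficients of the edges leaving input i), resid is w_in x w_out.
# Each input node carries its own spline domain (domains[i, ]) so the
# knot grid can track the range its activations actually occupy.
new_kan_layer <- function(w_in, w_out, grid_size, domain, init_sd = 0.1) {
  nb <- grid_size + 3
  list(
    w_in = w_in, w_out = w_out, grid_size = grid_size,
    domains = matrix(rep(domain, each = w_in), w_in, 2),
    knots = lapply(seq_len(w_in), function(i) kan_knots(domain, grid_size)),
    coef = lapply(seq_len(w_in), function(i)
      matrix(rnorm(nb * w_out, sd = init_sd / sqrt(w_in)), nb, w_out)),
    resid = matrix(1 / w_in, w_in, w_out)
  )
}

# forward pass through a layer; returns output and (optionally) a cache
# for backpropagation
kan_layer_forward <- function(layer, x, cache = FALSE) {
  n <- nrow(x)
  out <- matrix(0, n, layer$w_out)
  caches <- if (cache) vector("list", layer$w_in)
  for (i in seq_len(layer$w_in)) {
    dom <- layer$domains[i, ]
    xi <- pmin(dom[2], pmax(dom[1], x[, i]))
    B <- kan_basis(xi, layer$knots[[i]])
    s <- silu(xi)
    out <- out + B %*% layer$coef[[i]] +
      outer(s, layer$resid[i, ])
    if (cache) caches[[i]] <- list(xi = xi, B = B, s = s, raw = x[, i],
                                   inside = x[, i] >= dom[1] &
                                            x[, i] <= dom[2])
  }
  if (cache) list(out = out, caches = caches) else out
}

# Rebuild a layer's knot grids to the observed activation ranges and
# refit the spline coefficients by least squares so each edge function is
# preserved where it was already defined ("grid update").
kan_layer_regrid <- function(layer, x) {
  for (i in seq_len(layer$w_in)) {
    qs <- quantile(x[, i], c(0.001, 0.999), names = FALSE)
    pad <- 0.1 * max(diff(qs), 1e-3)
    dom_new <- c(qs[1] - pad, qs[2] + pad)
    knots_new <- kan_knots(dom_new, layer$grid_size)
    # sample the old edge functions on the new domain (clamped to the
    # old one, matching the evaluation contract) and refit
    xs <- seq(dom_new[1], dom_new[2], length.out = 25 * layer$grid_size)
    xs_old <- pmin(layer$domains[i, 2], pmax(layer$domains[i, 1], xs))
    f_old <- kan_basis(xs_old, layer$knots[[i]]) %*% layer$coef[[i]]
    B_new <- kan_basis(xs, knots_new)
    layer$coef[[i]] <- qr.solve(B_new, f_old)
    layer$domains[i, ] <- dom_new
    layer$knots[[i]] <- knots_new
  }
  layer
}

# backward pass: given dL/dout (n x w_out), accumulate parameter gradients
# and return dL/dx (n x w_in)
kan_layer_backward <- function(layer, fw, dout) {
  n <- nrow(dout)
  dx <- matrix(0, n, layer$w_in)
  dcoef <- vector("list", layer$w_in)
  dresid <- matrix(0, layer$w_in, layer$w_out)
  for (i in seq_len(layer$w_in)) {
    ca <- fw$caches[[i]]
    dcoef[[i]] <- crossprod(ca$B, dout)
    dresid[i, ] <- colSums(ca$s * dout)
    Bd <- kan_basis(ca$xi, layer$knots[[i]], deriv = 1)
    fprime <- Bd %*% layer$coef[[i]] +
      outer(silu_grad(ca$xi), layer$resid[i, ])
    gx <- rowSums(fprime * dout)
    gx[!ca$inside] <- 0  # clamped inputs carry no gradient
    dx[, i] <- gx
  }
  list(dx = dx, dcoef = dcoef, dresid = dresid)
}

new_kan_stage <- function(widths, grid_size, domains, init_sd = 0.1) {
  nl <- length(widths) - 1
  layers <- vector("list", nl)
  for (l in seq_len(nl)) {
    layers[[l]] <- new_kan_layer(widths[l], widths[l + 1], grid_size,
                                 domains[[l]], init_sd)
  }
  structure(list(widths = widths, layers = layers), class = "kan_stage")
}

kan_stage_forward <- function(stage, x, cache = FALSE) {
  fws <- if (cache) vector("list", length(stage$layers))
  for (l in seq_along(stage$layers)) {
    r <- kan_layer_forward(stage$layers[[l]], x, cache = cache)
    if (cache) { fws[[l]] <- r; x <- r$out } else x <- r
  }
  if (cache) list(out = x, fws = fws) else x
}

# ---- Surrogate model ----------------------------------------------------

#' Create an untrained two-stage KAN surrogate
#'
#' Stage 1 (layer widths 3-7-3) maps the normalized structural parameters
#' (\code{sigma_k}, \code{ln gamma}, \code{alpha}) to three latent
#' variables; stage 2 (widths 4-9-1-1, the trailing 1-1 layer acting as a
#' learned output warp) combines the latents with the dimensionless
#' momentum transfer \code{q} and predicts \code{log10} intensity. All
#' edges are cubic B-splines on uniform grids plus a fixed sigmoidal
#' residual term.
#'
#' @param ranges Named list of training ranges for \code{sigma_k},
#'   \code{ln_gamma}, \code{alpha}, \code{q}; inputs are affinely mapped
#'   to \eqn{[-1, 1]}.
#' @param grid_size Number of spline intervals per edge (default 10).
#' @param seed Seed for coefficient initialization.
#' @param residual Include the sigmoidal residual term (default TRUE).
#' @return An object of class \code{"kan_surrogate"}.
#' @export
kan_surrogate <- function(ranges = list(sigma_k = c(0.01, 0.5),
                                        ln_gamma = c(0, 5),
                                        alpha = c(0, 0.5),
                                        q = c(0.4, 3.6)),
                          grid_size = 10, seed = 1, residual = TRUE) {
  stopifnot(all(c("sigma_k", "ln_gamma", "alpha", "q") %in% names(ranges)))
  local_seed(seed, {
    hidden <- c(-4, 4)
    stage1 <- new_kan_stage(c(3, 7, 3), grid_size,
                            list(c(-1, 1), hidden))
    stage2 <- new_kan_stage(c(4, 9, 1, 1), grid_size,
                            list(c(-1, 1), hidden, hidden))
    m <- structure(
      list(stage1 = stage1, stage2 = stage2, ranges = ranges,
           grid_size = grid_size, residual = residual,
           out_shift = 0, out_scale = 1, trained = FALSE),
      class = "kan_surrogate"
    )
    if (!residual) {
      for (s in c("stage1", "stage2"))
        for (l in seq_along(m[[s]]$layers))
          m[[s]]$layers[[l]]$resid[] <- 0
    }
    m
  })
}

#' @export
print.kan_surrogate <- function(x, ...) {
  cat(sprintf(
    "KAN surrogate: stages [3,7,3] + [4,9,1,1], spline grid %d, %s\n",
    x$grid_size, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

kan_norm <- function(v, range) 2 * (v - range[1]) / (range[2] - range[1]) - 1

# forward pass on already-normalized inputs; X = n x 4 matrix of
# (sigma_k', ln_gamma', alpha', q'); returns the standardized network
# output (the affine output transform to log10 intensity is applied by
# the callers via model$out_shift / model$out_scale)
kan_forward_norm <- function(model, X, cache = FALSE) {
  s1 <- kan_stage_forward(model$stage1, X[, 1:3, drop = FALSE],
                          cache = cache)
  lat <- if (cache) s1$out else s1
  z <- cbind(lat, X[, 4])
  s2 <- kan_stage_forward(model$stage2, z, cache = cache)
  if (cache) list(out = s2$out[, 1], s1 = s1, s2 = s2)
  else s2[, 1]
}

#' Evaluate the KAN surrogate
#'
#' Predicts dimensionless scattering intensity at arbitrary (possibly
#' non-uniform) \code{q} values for one parameter triple. Inputs outside
#' the training ranges are clamped to the range boundary.
#'
#' @param model A \code{\link{kan_surrogate}}.
#' @param sigma_k,gamma,alpha Structural parameters (scalars);
#'   \code{gamma} is supplied on its natural scale and enters as
#'   \code{log(gamma)}.
#' @param q Numeric vector of dimensionless momentum transfer
#'   \eqn{Qd/2\pi}.
#' @param log10 Return \code{log10} intensity instead of intensity.
#' @return Numeric vector of intensities, one per \code{q}.
#' @export
kan_forward <- function(model, sigma_k, gamma, alpha, q, log10 = FALSE) {
  stopifnot(inherits(model, "kan_surrogate"))
  if (!all(is.finite(c(sigma_k, gamma, alpha, q))))
    stop("inputs must be finite")
  lg <- log(gamma)
  r <- model$ranges
  X <- cbind(
    kan_norm(rep(sigma_k, length(q)), r$sigma_k),
    kan_norm(rep(lg, length(q)), r$ln_gamma),
    kan_norm(rep(alpha, length(q)), r$alpha),
    kan_norm(q, r$q)
  )
  X[, 1:3] <- pmin(1, pmax(-1, X[, 1:3]))
  X[, 4] <- pmin(1, pmax(-1, X[, 4]))
  y <- kan_forward_norm(model, X) * model$out_scale + model$out_shift
  if (log10) y else 10^y
}

# flatten / unflatten parameters for the optimizer
kan_params_flat <- function(model) {
  unlist(lapply(c("stage1", "stage2"), function(s)
    lapply(model[[s]]$layers, function(l) c(unlist(l$coef), l$resid))))
}

kan_params_assign <- function(model, theta) {
  pos <- 1
  for (s in c("stage1", "stage2")) {
    for (l in seq_along(model[[s]]$layers)) {
      lay <- model[[s]]$layers[[l]]
      for (i in seq_len(lay$w_in)) {
        np <- length(lay$coef[[i]])
        lay$coef[[i]][] <- theta[pos:(pos + np - 1)]
        pos <- pos + np
      }
      np <- length(lay$resid)
      lay$resid[] <- theta[pos:(pos + np - 1)]
      pos <- pos + np
      model[[s]]$layers[[l]] <- lay
    }
  }
  model
}

# loss and gradient on normalized inputs X (n x 4) and targets y
# (standardized log10 I). lambda adds a P-spline roughness penalty
# (squared second differences of every edge's coefficients), the
# standard smoothness regularizer for uniform-knot splines.
kan_loss_grad <- function(model, X, y, weights = NULL, lambda = 0) {
  fw <- kan_forward_norm(model, X, cache = TRUE)
  r <- fw$out - y
  w <- weights %||% rep(1, length(y))
  loss <- mean(w * r^2)
  dout <- matrix(2 * w * r / length(y), ncol = 1)

  grads <- list()
  # stage 2 backward
  dx <- dout
  s2grads <- vector("list", length(model$stage2$layers))
  for (l in rev(seq_along(model$stage2$layers))) {
    bk <- kan_layer_backward(model$stage2$layers[[l]], fw$s2$fws[[l]], dx)
    s2grads[[l]] <- bk
    dx <- bk$dx
  }
  # latent gradient flows into stage 1 (first 3 columns of stage-2 input)
  dlat <- dx[, 1:3, drop = FALSE]
  s1grads <- vector("list", length(model$stage1$layers))
  dx <- dlat
  for (l in rev(seq_along(model$stage1$layers))) {
    bk <- kan_layer_backward(model$stage1$layers[[l]], fw$s1$fws[[l]], dx)
    s1grads[[l]] <- bk
    dx <- bk$dx
  }
  g <- c(
    unlist(lapply(seq_along(s1grads), function(l)
      c(unlist(s1grads[[l]]$dcoef), s1grads[[l]]$dresid))),
    unlist(lapply(seq_along(s2grads), function(l)
      c(unlist(s2grads[[l]]$dcoef), s2grads[[l]]$dresid)))
  )
  if (lambda > 0) {
    # penalty gradients in the same flattening order as g:
    # d/dc ||D2 c||^2 = 2 t(D2) D2 c
    pen <- 0
    gpen <- numeric(length(g))
    pos <- 1
    for (st in c("stage1", "stage2")) {
      for (l in seq_along(model[[st]]$layers)) {
        lay <- model[[st]]$layers[[l]]
        for (i in seq_len(lay$w_in)) {
          cf <- lay$coef[[i]]
          d2 <- diff(cf, differences = 2)
          pen <- pen + sum(d2^2)
          gcf <- matrix(0, nrow(cf), ncol(cf))
          gcf[1:(nrow(cf) - 2), ] <- gcf[1:(nrow(cf) - 2), ] + d2
          gcf[2:(nrow(cf) - 1), ] <- gcf[2:(nrow(cf) - 1), ] - 2 * d2
          gcf[3:nrow(cf), ] <- gcf[3:nrow(cf), ] + d2
          np <- length(cf)
          gpen[pos:(pos + np - 1)] <- 2 * lambda * as.numeric(gcf)
          pos <- pos + np
        }
        pos <- pos + length(lay$resid)
      }
    }
    loss <- loss + lambda * pen
    g <- g + gpen
  }
  list(loss = loss, grad = g)
}

#' Train the KAN surrogate on a spectrum library
#'
#' Minimizes mean squared error in \code{log10} intensity by full-batch
#' Adam with early stopping on validation loss; the snapshot with the best
#' validation loss is returned. Deterministic given \code{seed}.
#'
#' @param model A \code{\link{kan_surrogate}}.
#' @param library A \code{\link{make_library}} result (or any list with
#'   \code{params} data frame and \code{spectra} list).
#' @param epochs Maximum number of epochs (default 2000).
#' @param lr Adam step size (default 0.02).
#' @param patience Early-stopping patience on validation loss
#'   (default 50).
#' @param grid_update_at Epochs at which every layer's knot grids are
#'   rebuilt to the observed activation ranges (coefficients refitted by
#'   least squares so the learned edge functions are preserved).
#' @param lambda P-spline roughness penalty weight (squared second
#'   differences of every edge's coefficients); the smoothness
#'   regularizer that controls generalization once the quasi-Newton
#'   polish drives the training loss down. Default \code{1e-3}.
#' @param polish After Adam converges, refine with chunks of L-BFGS
#'   iterations on the full batch, keeping the best-validation snapshot
#'   (default TRUE).
#' @param seed Seed controlling the train/validation shuffling.
#' @param q_window Dimensionless q range of points used (default the
#'   model's q range).
#' @param verbose Print progress every 100 epochs.
#' @return The trained model; the loss history is attached as attribute
#'   \code{"history"} (data frame epoch/train/validation).
#' @export
kan_train <- function(model, library, epochs = 2000, lr = 0.01,
                      patience = 120, grid_update_at = c(30, 100, 250),
                      lambda = 1e-3, polish = TRUE,
                      seed = 1, q_window = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "kan_surrogate"))
  if (nrow(library$params) < 2) stop("library needs >= 2 distinct triples")
  dat <- kan_training_matrix(model, library, q_window)
  X <- dat$X; y <- dat$y
  split <- library$split %||% rep("train", nrow(library$params))
  take <- function(lbl) dat$triple %in% which(split == lbl)
  itr <- take("train"); iva <- take("validation")
  if (!any(iva)) { iva <- itr; }  # tiny libraries: validate on train

  # standardize the regression target (log10 intensity spans decades);
  # the affine transform is stored on the model and inverted on output
  model$out_shift <- mean(y[itr])
  model$out_scale <- max(sd(y[itr]), 1e-8)
  y <- (y - model$out_shift) / model$out_scale

  # heteroscedastic weights: bins with large ensemble uncertainty (deep
  # minima) count less; a floor of 0.02 log10-decades represents the
  # irreducible model error so no point dominates
  w <- dat$sigma_log
  if (all(is.na(w))) w <- rep(1, length(y)) else {
    w[!is.finite(w)] <- max(w[is.finite(w)], 0.1)
    w <- 1 / (w^2 + 0.02^2) / model$out_scale^2
    w <- w / mean(w[itr])
  }

  theta <- kan_params_flat(model)
  m1 <- v1 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, model = model, epoch = 0)
  hist_l <- matrix(NA_real_, epochs, 2)
  Xtr <- X[itr, , drop = FALSE]; ytr <- y[itr]; wtr <- w[itr]
  Xva <- X[iva, , drop = FALSE]; yva <- y[iva]
  wait <- 0
  plateau <- max(10, floor(patience / 2))

  regrid <- function(model) {
    fw <- kan_forward_norm(model, Xtr, cache = TRUE)
    for (s in c("stage1", "stage2")) {
      fws <- if (s == "stage1") fw$s1$fws else fw$s2$fws
      for (l in seq_along(model[[s]]$layers)) {
        xmat <- vapply(fws[[l]]$caches, `[[`, numeric(nrow(Xtr)), "raw")
        model[[s]]$layers[[l]] <- kan_layer_regrid(model[[s]]$layers[[l]],
                                                   xmat)
      }
    }
    model
  }

  for (e in seq_len(epochs)) {
    model <- kan_params_assign(model, theta)
    if (e %in% grid_update_at) {
      model <- regrid(model)
      theta <- kan_params_flat(model)
      m1 <- v1 <- numeric(length(theta))
      va <- mean((kan_forward_norm(model, Xva) - yva)^2)
      best <- list(loss = va, model = model, epoch = e)
      wait <- 0
    }
    lg <- kan_loss_grad(model, Xtr, ytr, weights = wtr, lambda = lambda)
    if (!is.finite(lg$loss)) stop("training diverged: non-finite loss")
    va <- mean((kan_forward_norm(model, Xva) - yva)^2)
    hist_l[e, ] <- c(lg$loss, va)
    if (va < best$loss * (1 - 1e-4)) {
      best <- list(loss = va, model = model, epoch = e)
      wait <- 0
    } else {
      wait <- wait + 1
      # reduce-on-plateau: halve the step, restart from the best
      # snapshot, and give the smaller step a fresh patience window
      if (wait >= plateau) {
        lr <- lr / 2
        theta <- kan_params_flat(best$model)
        m1 <- v1 <- numeric(length(theta))
        wait <- 0
      }
    }
    if (lr < 2e-4) break
    m1 <- b1 * m1 + (1 - b1) * lg$grad
    v1 <- b2 * v1 + (1 - b2) * lg$grad^2
    mh <- m1 / (1 - b1^e); vh <- v1 / (1 - b2^e)
    theta <- theta - lr * mh / (sqrt(vh) + eps)
    if (verbose && e %% 100 == 0)
      message(sprintf("epoch %d: train %.5f, val %.5f", e, lg$loss, va))
  }
  model <- best$model

  if (polish) {
    # quasi-Newton refinement: full-batch L-BFGS in chunks, keeping the
    # best-validation snapshot; the roughness penalty supplies the
    # regularization that early stopping provided during Adam
    work <- model
    th <- kan_params_flat(work)
    fn <- function(p) {
      kan_loss_grad(kan_params_assign(work, p), Xtr, ytr,
                    weights = wtr, lambda = lambda)$loss
    }
    gr <- function(p) {
      kan_loss_grad(kan_params_assign(work, p), Xtr, ytr,
                    weights = wtr, lambda = lambda)$grad
    }
    stale <- 0
    for (chunk in seq_len(12)) {
      o <- tryCatch(
        optim(th, fn, gr, method = "L-BFGS-B",
              control = list(maxit = 150)),
        error = function(e) NULL)
      if (is.null(o)) break
      th <- o$par
      cand <- kan_params_assign(work, th)
      va <- mean((kan_forward_norm(cand, Xva) - yva)^2)
      if (verbose)
        message(sprintf("polish %d: train %.5f, val %.5f", chunk,
                        o$value, va))
      if (va < best$loss * (1 - 1e-4)) {
        best <- list(loss = va, model = cand, epoch = best$epoch)
        stale <- 0
      } else stale <- stale + 1
      if (stale >= 3 || o$convergence == 0) break
    }
    model <- best$model
  }

  model$trained <- TRUE
  hist_df <- data.frame(epoch = seq_len(e),
                        train = hist_l[seq_len(e), 1],
                        validation = hist_l[seq_len(e), 2])
  attr(model, "history") <- hist_df
  attr(model, "best_epoch") <- best$epoch
  model
}

# assemble the (normalized X, log10 y) training matrix from a library,
# with per-point uncertainties propagated to log10 scale
kan_training_matrix <- function(model, library, q_window = NULL) {
  r <- model$ranges
  if (is.null(q_window)) q_window <- r$q
  Xs <- list(); ys <- list(); tr <- list(); ss <- list()
  for (i in seq_len(nrow(library$params))) {
    p <- library$params[i, ]
    sp <- library$spectra[[i]]
    keep <- sp$q >= q_window[1] & sp$q <= q_window[2] & sp$intensity > 0
    qv <- sp$q[keep]
    Xs[[i]] <- cbind(
      kan_norm(rep(p$sigma_k, length(qv)), r$sigma_k),
      kan_norm(rep(log(p$gamma), length(qv)), r$ln_gamma),
      kan_norm(rep(p$alpha, length(qv)), r$alpha),
      kan_norm(qv, r$q)
    )
    ys[[i]] <- log10(sp$intensity[keep])
    un <- sp$uncertainty
    sl <- if (is.null(un) || all(!is.finite(un))) rep(NA_real_, sum(keep))
          else (un[keep] / sp$intensity[keep]) / log(10)
    ss[[i]] <- sl
    tr[[i]] <- rep(i, length(qv))
  }
  list(X = do.call(rbind, Xs), y = unlist(ys), triple = unlist(tr),
       sigma_log = unlist(ss))
}

#' Generate a training library of GLW spectra
#'
#' Samples parameter triples (\code{sigma_k}, \code{ln gamma},
#' \code{alpha}) by maximin Latin hypercube over the training ranges and
#' computes an ensemble-averaged spectrum for each with the GLW simulator.
#' Spectrum seeds are derived from \code{seed} by fixed offsets, so the
#' design is unchanged when \code{n_real} changes.
#'
#' @param n_samples Number of parameter triples (>= 10).
#' @param ranges Named list of ranges for \code{sigma_k}, \code{ln_gamma},
#'   \code{alpha}.
#' @param grid_n Simulation grid per axis (default 64).
#' @param n_real Realizations per spectrum (default 3).
#' @param d Mean spacing used in simulation (arbitrary; spectra are
#'   dimensionless).
#' @param n_waves Partial waves per field.
#' @param seed Master seed.
#' @param split Proportions of train/validation/test labels.
#' @param progress Print a dot every 10 spectra.
#' @return A \code{"glw_library"}: list with \code{params} (data frame of
#'   \code{sigma_k}, \code{gamma}, \code{alpha}), \code{spectra} (list of
#'   \code{"glw_spectrum"}), \code{split} (labels), \code{seed}.
#' @export
make_library <- function(n_samples, ranges = list(sigma_k = c(0.01, 0.5),
                                                  ln_gamma = c(0, 5),
                                                  alpha = c(0, 0.5)),
                         grid_n = 64, n_real = 3, d = 40, n_waves = 1000,
                         seed = 1, split = c(train = 0.8,
                                             validation = 0.1,
                                             test = 0.1),
                         progress = FALSE) {
  if (n_samples < 10) stop("'n_samples' must be >= 10")
  design <- local_seed(seed, lhs::randomLHS(n_samples, 3))
  params <- data.frame(
    sigma_k = ranges$sigma_k[1] + design[, 1] * diff(ranges$sigma_k),
    gamma = exp(ranges$ln_gamma[1] + design[, 2] * diff(ranges$ln_gamma)),
    alpha = ranges$alpha[1] + design[, 3] * diff(ranges$alpha)
  )
  labels <- local_seed(seed + 1L, {
    lab <- rep(names(split), round(split * n_samples))
    lab <- c(lab, rep("train", n_samples - length(lab)))
    sample(lab[seq_len(n_samples)])
  })
  spectra <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    m <- glw_model(params$sigma_k[i], params$gamma[i], params$alpha[i],
                   d = d, n_waves = n_waves, grid_n = grid_n,
                   seed = seed + 1000L + i * 100L)
    spectra[[i]] <- ensemble_spectrum(m, n_real = n_real)
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(
    list(params = params, spectra = spectra, split = labels,
         ranges = ranges, grid_n = grid_n, n_real = n_real,
         n_waves = n_waves, d = d, seed = seed),
    class = "glw_library"
  )
}

#' @export
print.glw_library <- function(x, ...) {
  cat(sprintf("GLW spectrum library: %d triples, grid %d^3, %d real each\n",
              nrow(x$params), x$grid_n, x$n_real))
  invisible(x)
}
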