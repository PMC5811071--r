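# C-alpha principal component analysis of the transporter core, trajectory
# projections, cosine-content diagnostics and extreme-structure export.

# extract selection coordinates of every frame as F x 3n matrix
selection_xyz <- function(traj, inds) {
  traj$xyz[, bio3d::atom2xyz(inds), drop = FALSE]
}

# fit each row of X (F x 3n) onto the 3n reference vector, fitting on all
# atoms of the (sub-)system
fit_rows <- function(X, ref) {
  n <- length(ref) / 3
  xi <- seq_len(length(ref))
  bio3d::fit.xyz(fixed = ref, mobile = X, fixed.inds = xi, mobile.inds = xi)
}

#' Fit a principal component model to a trajectory
#'
#' Frames are superposed onto their iteratively recomputed mean over the
#' selection (the selection itself is the fit set; 2 mean-fit iterations),
#' then the 3N-dimensional covariance of the centred coordinates is
#' eigendecomposed. Eigenvectors are orthonormal in descending eigenvalue
#' order; the eigenvalue sum equals the total positional variance of the
#' superposed ensemble.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param top The matching [topology()].
#' @param sel A [selection()] resolving to Cα atoms only (e.g. the
#'   `pca_core` preset as [ca_selection()]).
#' @param n_iter Mean-fit iterations (default 2).
#' @return Object of class `PCAModel`: `mean` (3n vector), `vectors`
#'   (3n x m orthonormal), `values` (Ų, non-increasing), `projections`
#'   (F x m, of the fitting ensemble), `inds` (atom indices),
#'   `fit_protocol`.
#' @export
fit_pca <- function(traj, top, sel, n_iter = 2) {
  if (traj$nframes < 2) stop(mp_error("pca", "need at least 2 frames"))
  inds <- resolve_selection(top, sel)
  if (any(top$atoms$name[inds] != "CA")) {
    stop(mp_error("selection", "PCA selection must resolve to CA atoms only"))
  }
  X <- selection_xyz(traj, inds)
  ref <- X[1, ]
  for (it in seq_len(n_iter)) {
    X <- fit_rows(X, ref)
    if (!is.matrix(X)) X <- matrix(X, nrow = 1)
    ref <- colMeans(X)
  }
  Xc <- sweep(X, 2, ref)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(mean = ref, vectors = e$vectors, values = vals,
                 projections = Xc %*% e$vectors, inds = inds,
                 fit_protocol = sprintf("iterated-mean-%d", n_iter)),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "PCAModel: %d atoms, %d frames fitted (%s)\n  eigenvalue sum %.4g A^2; PC1 %.1f%%, PC2 %.1f%%\n",
    length(x$inds), nrow(x$projections), x$fit_protocol, sum(v),
    100 * v[1] / sum(v), 100 * v[2] / sum(v)))
  invisible(x)
}

#' Project a trajectory onto one eigenvector
#'
#' Each frame is superposed onto the model mean over the model selection,
#' centred, and dotted with the requested eigenvector. Projecting a
#' trajectory from a different topology requires an explicit residue
#' correspondence (`index_map`); without one the projection is refused.
#'
#' @param traj A [trajectory()].
#' @param model A [fit_pca()] model.
#' @param index Eigenvector index (1-based).
#' @param top The trajectory's [topology()]; must be the fitting topology
#'   unless `index_map` gives the atom correspondence.
#' @param index_map Optional integer vector: for each model selection atom,
#'   the matching atom index in `top`.
#' @return Object of class `ProjectionSeries`: `values` (Å), `index`,
#'   `time`, `cosine_content`.
#' @export
project <- function(traj, model, index = 1, top = NULL, index_map = NULL) {
  if (index < 1 || index > ncol(model$vectors)) {
    stop(mp_error("pca", "eigenvector index %d out of range 1..%d", index,
                  ncol(model$vectors)))
  }
  inds <- if (!is.null(index_map)) index_map else model$inds
  if (3 * length(inds) != length(model$mean)) {
    stop(mp_error("pca", "atom correspondence does not match the model"))
  }
  if (max(inds) > traj$natoms) {
    stop(mp_error("pca", paste0(
      "trajectory topology incompatible with the model selection; supply ",
      "index_map for a cross-topology projection")))
  }
  X <- fit_rows(selection_xyz(traj, inds), model$mean)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  p <- as.vector(sweep(X, 2, model$mean) %*% model$vectors[, index])
  cc <- if (length(p) >= 4 && any(p != 0)) cosine_content(p, index,
                                                          traj$time) else NA
  structure(list(values = p, index = index, time = traj$time,
                 cosine_content = cc),
            class = "ProjectionSeries")
}

#' Cosine content of a projection series
#'
#' Diagnostic comparing a principal-component projection to a cosine of
#' matching index: `c_i = (2/T) (∫ p(t) cos(iπt/T) dt)² / ∫ p(t)² dt`,
#' evaluated with trapezoidal sums on the series' time axis and clamped to
#' \[0, 1\]. Values near 1 indicate random-diffusion-like sampling.
#'
#' @param series A `ProjectionSeries` or numeric vector (length >= 4, not
#'   all zero).
#' @param index Cosine index `i`; defaults to the series' eigenvector index.
#' @param time Time axis; defaults to the series' (or `0:(n-1)`).
#' @return Fraction in \[0, 1\].
#' @export
cosine_content <- function(series, index = NULL, time = NULL) {
  if (inherits(series, "ProjectionSeries")) {
    index <- index %||% series$index
    time <- time %||% series$time
    p <- series$values
  } else {
    p <- as.numeric(series)
    index <- index %||% 1
  }
  n <- length(p)
  if (n < 4) stop(mp_error("pca", "series too short for cosine content"))
  if (all(p == 0)) {
    stop(mp_error("pca", "cosine content undefined for an all-zero series"))
  }
  t <- time %||% (seq_len(n) - 1)
  t <- t - t[1]
  T <- t[n]
  num <- pracma::trapz(t, p * cos(index * pi * t / T))
  den <- pracma::trapz(t, p^2)
  cc <- (2 / T) * num^2 / den
  min(1, max(0, cc))
}

#' Extreme structures along one eigenvector
#'
#' The model mean displaced to the two extremes of the fitted projection
#' range (or a symmetric ±amplitude), for porcupine-style visualisation of
#' the component.
#'
#' @param model A [fit_pca()] model.
#' @param index Eigenvector index.
#' @param amplitude Either `NULL` (use `min`/`max` of the fitting
#'   projections) or a single non-negative number used as ±amplitude.
#' @return List: `lower`, `upper` (n x 3 coordinate matrices),
#'   `displacement` (n x 3 per-atom vectors of the unit eigenvector),
#'   `amplitudes` (the two scalars used).
#' @export
extreme_structures <- function(model, index = 1, amplitude = NULL) {
  v <- model$vectors[, index]
  amps <- if (is.null(amplitude)) {
    range(model$projections[, index])
  } else {
    c(-abs(amplitude), abs(amplitude))
  }
  to3 <- function(x) matrix(x, ncol = 3, byrow = TRUE)
  list(lower = to3(model$mean + amps[1] * v),
       upper = to3(model$mean + amps[2] * v),
       displacement = to3(v), amplitudes = amps)
}

#' Write extreme structures as a two-model PDB
#'
#' @param ext An [extreme_structures()] result.
#' @param model The [fit_pca()] model it came from.
#' @param top The fitting [topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extremes_pdb <- function(ext, model, top, path) {
  sub <- subset_topology(top, model$inds)
  xyz <- rbind(as.vector(t(ext$lower)), as.vector(t(ext$upper)))
  write_trajectory_pdb(trajectory(xyz, c(1000, 1000, 1000)), sub, path)
}

#' Restrict a topology to a set of atoms
#' @param top A [topology()].
#' @param indices Atom indices to keep.
#' @return A new [topology()] (reference coordinates subset when present).
#' @export
subset_topology <- function(top, indices) {
  suppressWarnings(topology(top$atoms[indices, c("eleno", "name", "element",
                                                 "resno", "resid", "chain")],
                            xyz = if (is.null(top$xyz)) NULL else
                              top$xyz[indices, , drop = FALSE]))
}
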