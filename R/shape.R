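# Point-distribution shape model: Procrustes alignment, PCA with similarity
# augmentation, model evaluation and the translational shape Jacobian.

# Orientation canonicalization for the Procrustes mean: rotate so that the
# principal axis of the point cloud lies along x, resolving the 180-degree
# ambiguity by the sign of the x coordinate of the farthest point. Makes the
# converged mean independent of the input ordering.
canonical_rotation <- function(M) {
  Cm <- crossprod(M) / nrow(M)
  ev <- eigen(Cm, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  ang <- atan2(v[2L], v[1L])
  R <- matrix(c(cos(-ang), -sin(-ang), sin(-ang), cos(-ang)), 2L, 2L, byrow = TRUE)
  Mr <- M %*% t(R)
  k <- which.max(rowSums(Mr^2))
  if (Mr[k, 1L] < 0) {
    R <- -R  # rotate by a further 180 degrees
    Mr <- -Mr
  }
  # fix the remaining y reflection-like ambiguity of the axis choice by the
  # sign of the largest |y| coordinate (a pure rotation by 180 only, so this
  # is still a proper rotation overall)
  list(R = R, M = Mr)
}

# Optimal similarity (rotation + uniform scale) of centered shape X onto
# centered reference M, minimizing ||s X R - M||_F. Proper rotations only.
align_centered <- function(X, M) {
  C <- crossprod(X, M)
  sv <- svd(C)
  d <- c(1, sign(det(sv$u %*% t(sv$v))))
  R <- sv$u %*% diag(d) %*% t(sv$v)
  s <- sum(sv$d * d) / sum(X^2)
  list(R = R, s = s, aligned = s * X %*% R)
}

#' Generalized Procrustes alignment of landmark sets
#'
#' Removes similarity transforms (translation, rotation, uniform scale) from a
#' collection of landmark sets by iterative alignment to a running mean. Each
#' shape is centered at its centroid; the mean is renormalized to unit
#' Frobenius norm at every iteration and its orientation is canonicalized so
#' the result does not depend on the input order. Iteration stops when the
#' mean changes by less than `tol` (Frobenius norm) or after `max_iter`
#' iterations.
#'
#' @param shapes list of landmark vectors (interleaved `[x1,y1,...]`), all
#'   with the same number of points.
#' @param tol convergence tolerance on the mean change (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return list with `aligned` (list of aligned landmark vectors), `mean`
#'   (unit-norm mean landmark vector) and `mean_scale` (mean centroid size of
#'   the input shapes, useful for restoring pixel units).
#' @export
procrustes_align <- function(shapes, tol = 1e-10, max_iter = 100L) {
  if (!is.list(shapes) || length(shapes) < 2L) {
    stop("need at least 2 shapes", call. = FALSE)
  }
  u <- length(shapes[[1L]]) / 2L
  mats <- lapply(shapes, function(s) {
    check_landmarks(s, u = u)
    M <- lmk_matrix(s)
    sweep(M, 2L, colMeans(M))
  })
  norms <- vapply(mats, function(M) sqrt(sum(M^2)), numeric(1))
  if (any(norms < 1e-12)) stop("degenerate shape with zero scale", call. = FALSE)

  ref <- mats[[1L]] / norms[1L]
  ref <- canonical_rotation(ref)$M
  aligned <- mats
  for (it in seq_len(max_iter)) {
    aligned <- lapply(mats, function(M) align_centered(M, ref)$aligned)
    newmean <- Reduce(`+`, aligned) / length(aligned)
    newmean <- newmean / sqrt(sum(newmean^2))
    newmean <- canonical_rotation(newmean)$M
    delta <- sqrt(sum((newmean - ref)^2))
    ref <- newmean
    if (delta < tol) break
  }
  aligned <- lapply(mats, function(M) align_centered(M, ref)$aligned)
  list(
    aligned = lapply(aligned, lmk_vector),
    mean = lmk_vector(ref),
    mean_scale = mean(norms)
  )
}

# The 4 similarity basis vectors generated from s0: scale (s0 itself),
# in-plane rotation ([-y, x] per point), x translation and y translation;
# orthonormalized in that order.
similarity_basis <- function(s0) {
  u <- length(s0) / 2L
  M <- lmk_matrix(s0)
  b1 <- s0
  b2 <- lmk_vector(cbind(-M[, 2L], M[, 1L]))
  b3 <- rep(c(1, 0), u)
  b4 <- rep(c(0, 1), u)
  B <- cbind(b1, b2, b3, b4)
  Q <- qr.Q(qr(B))
  canonical_sign(Q[, seq_len(min(4L, ncol(Q))), drop = FALSE])
}

#' Build a linear point-distribution shape model
#'
#' Runs PCA on aligned landmark sets and augments the deformation basis with
#' 4 similarity eigenvectors derived from the mean shape (scale, rotation and
#' the two translations), re-orthonormalizing the joint basis. The returned
#' basis `S` has `n_pca + 4` orthonormal columns: the 4 similarity columns
#' first, then the PCA deformation modes.
#'
#' @param aligned list of aligned landmark vectors (typically from
#'   [procrustes_align()], rescaled to pixel units by the caller if desired).
#' @param n_pca number of PCA deformation components to retain; must satisfy
#'   `n_pca <= D - 1` and `n_pca <= 2u - 4`.
#' @return an object of class `shape_model`: list with `s0` (mean shape,
#'   length 2u), `S` (2u x n orthonormal basis), `eigenvalues` (length n,
#'   similarity block then PCA block, each non-increasing), `u`, `n`,
#'   `n_sim = 4`, and `normalization` metadata.
#' @export
build_shape_model <- function(aligned, n_pca) {
  D <- length(aligned)
  u <- length(aligned[[1L]]) / 2L
  if (n_pca > D - 1L || n_pca > 2L * u - 4L) {
    stop(sprintf("n_pca = %d too large for D = %d shapes with u = %d points",
                 n_pca, D, u), call. = FALSE)
  }
  X <- do.call(rbind, aligned)
  s0 <- colMeans(X)
  Xc <- sweep(X, 2L, s0)
  sv <- svd(Xc, nu = 0L)
  V <- sv$v[, seq_len(n_pca), drop = FALSE]

  sim <- similarity_basis(s0)
  # orthogonalize the PCA block against the similarity block, then
  # re-orthonormalize; drop of rank is an error (caller asked for too much)
  Vo <- V - sim %*% crossprod(sim, V)
  qv <- qr(Vo)
  if (qv$rank < n_pca) {
    stop("PCA block is rank-deficient after similarity augmentation", call. = FALSE)
  }
  Vq <- canonical_sign(qr.Q(qv)[, seq_len(n_pca), drop = FALSE])
  S <- cbind(sim, Vq)
  colnames(S) <- NULL

  proj <- Xc %*% S
  evals <- colSums(proj^2) / max(1L, D - 1L)
  ord_sim <- order(evals[1:4], decreasing = TRUE)
  ord_pca <- 4L + order(evals[-(1:4)], decreasing = TRUE)
  S <- S[, c(ord_sim, ord_pca), drop = FALSE]
  evals <- evals[c(ord_sim, ord_pca)]

  structure(list(
    s0 = s0, S = S, eigenvalues = evals,
    u = u, n = ncol(S), n_sim = 4L,
    normalization = "centroid-centered, unit-Frobenius Procrustes mean"
  ), class = "shape_model")
}

# Assemble a shape_model directly from its pieces (used by the synthetic
# generator and tests). Orthonormality is checked.
shape_model_from_basis <- function(s0, S, eigenvalues = NULL, n_sim = 4L) {
  G <- crossprod(S)
  if (max(abs(G - diag(ncol(S)))) > 1e-8) {
    stop("shape basis is not orthonormal", call. = FALSE)
  }
  structure(list(
    s0 = s0, S = S,
    eigenvalues = if (is.null(eigenvalues)) rep(0, ncol(S)) else eigenvalues,
    u = length(s0) / 2L, n = ncol(S), n_sim = n_sim,
    normalization = "explicit"
  ), class = "shape_model")
}

#' Evaluate a shape model instance
#'
#' Returns `s0 + S p`.
#'
#' @param model a `shape_model`.
#' @param p parameter vector of length `model$n`.
#' @return landmark vector of length 2u.
#' @export
shape_instance <- function(model, p) {
  if (length(p) != model$n || !all(is.finite(p))) {
    stop(sprintf("p must be a finite vector of length %d", model$n), call. = FALSE)
  }
  drop(model$s0 + model$S %*% p)
}

#' Project a landmark set onto a shape model
#'
#' Returns `S^T (shape - s0)`, the coefficients of the orthogonal projection
#' of the shape onto the model subspace.
#'
#' @param model a `shape_model`.
#' @param shape landmark vector of length 2u.
#' @return parameter vector of length `model$n`.
#' @export
project_shape <- function(model, shape) {
  check_landmarks(shape, u = model$u)
  drop(crossprod(model$S, shape - model$s0))
}

#' Per-landmark translational shape Jacobians
#'
#' For every landmark k returns the 2 x n matrix of partial derivatives of
#' the landmark position with respect to the shape parameters at p = 0: the
#' x row holds the x components of each basis column at landmark k, the y row
#' the y components. Stacking the per-landmark blocks row-wise reproduces a
#' row permutation of `S`.
#'
#' @param model a `shape_model`.
#' @return list of u matrices, each 2 x n.
#' @export
translational_shape_jacobian <- function(model) {
  S <- model$S
  lapply(seq_len(model$u), function(k) {
    rbind(S[2L * k - 1L, ], S[2L * k, ])
  })
}
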