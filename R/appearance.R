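# Appearance models: holistic (shape-free textures on the reference-frame
# mask), part-based (concatenated per-landmark patches), multi-channel
# layouts, steepest-descent images and the matrix-free projector.

# PCA of a D x q data matrix (rows = observations). Returns mean, the first
# m sign-canonicalized right singular vectors and the sample eigenvalues.
pca_fit <- function(X, m) {
  D <- nrow(X)
  if (m > D - 1L) stop(sprintf("m = %d too large for D = %d samples", m, D), call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0L)
  evals <- sv$d^2 / max(1L, D - 1L)
  basis <- canonical_sign(sv$v[, seq_len(m), drop = FALSE])
  list(mean = mu, basis = basis, eigenvalues = evals[seq_len(m)], all_eigenvalues = evals)
}

new_appearance_model <- function(A0, A, eigenvalues, layout, C) {
  structure(list(
    A0 = A0, A = A, eigenvalues = eigenvalues,
    layout = layout, C = C, m = ncol(A), N = length(A0) / C
  ), class = "appearance_model")
}

#' Build a holistic appearance model
#'
#' Warps every training image into the reference frame, runs PCA on the
#' resulting N*C sample vectors and keeps `m` components. No per-pixel
#' variance normalization is applied: the model is built on raw sample
#' values (intensities or descriptor channels).
#'
#' @param images list of image matrices / arrays.
#' @param landmarks list of landmark vectors, one per image.
#' @param frame the `ref_frame` of the mean shape.
#' @param m number of appearance components (`m <= D - 1`).
#' @return an `appearance_model` with holistic layout.
#' @export
build_holistic_appearance <- function(images, landmarks, frame, m) {
  stopifnot(length(images) == length(landmarks), length(images) >= 2L)
  vecs <- mapply(function(img, lmk) {
    flatten_samples(warp_image(img, lmk, frame))
  }, images, landmarks, SIMPLIFY = FALSE)
  C <- length(vecs[[1L]]) / frame$N
  X <- do.call(rbind, vecs)
  fit <- pca_fit(X, m)
  new_appearance_model(fit$mean, fit$basis, fit$eigenvalues,
                       layout = list(kind = "holistic", frame = frame), C = as.integer(C))
}

# Similarity transform (scale s, rotation R, translation t) mapping image
# landmarks onto reference landmarks: x_ref = s * R %*% x_img + t.
similarity_to_reference <- function(lmk, ref) {
  X <- lmk_matrix(lmk); M <- lmk_matrix(ref)
  cx <- colMeans(X); cm <- colMeans(M)
  al <- align_centered(sweep(X, 2L, cx), sweep(M, 2L, cm))
  # aligned = s * Xc %*% R, i.e. x_ref = s * t(R) %*% ... careful: row-vector form
  list(s = al$s, R = t(al$R), t = cm - al$s * drop(cx %*% al$R))
}

# Patch grid offsets for an N_s x N_s patch, within-patch row-major
# (dy outer loop, dx inner), centered at 0.
patch_offsets <- function(N_s) {
  h <- (N_s - 1L) / 2L
  d <- seq.int(-h, h)
  cbind(dx = rep(d, times = N_s), dy = rep(d, each = N_s))
}

# Sample the u patches of one image: landmarks in image coordinates, patch
# axes similarity-normalized to the reference shape. Returns (u * N_s^2) x C
# matrix, parts concatenated in landmark order.
sample_parts <- function(image, lmk, ref, N_s) {
  sim <- similarity_to_reference(lmk, ref)
  # image-space offset for a reference-space offset d: (1/s) R^T d
  Rinv <- t(sim$R) / sim$s
  offs <- patch_offsets(N_s)
  offs_img <- offs %*% t(Rinv)
  L <- lmk_matrix(lmk)
  xs <- rep(L[, 1L], each = nrow(offs)) + rep(offs_img[, 1L], times = nrow(L))
  ys <- rep(L[, 2L], each = nrow(offs)) + rep(offs_img[, 2L], times = nrow(L))
  sample_channels(image, xs, ys)
}

#' Build a part-based appearance model
#'
#' Similarity-normalizes each training image to the reference scale, extracts
#' the N_s x N_s patch centered at each landmark, concatenates the patches in
#' landmark order (within-patch row-major) and applies PCA. With `N_s = 1`
#' the model degenerates to the single-pixel-per-landmark model of the
#' translational motion formulation.
#'
#' @param images,landmarks training set as in [build_holistic_appearance()].
#' @param model the `shape_model` providing the reference mean shape.
#' @param N_s odd patch side length in reference pixels (default 19).
#' @param m number of appearance components.
#' @return an `appearance_model` with parts layout.
#' @export
build_part_appearance <- function(images, landmarks, model, N_s = 19L, m) {
  stopifnot(length(images) == length(landmarks), length(images) >= 2L)
  if (N_s %% 2L != 1L) stop("N_s must be odd (centered patches)", call. = FALSE)
  vecs <- mapply(function(img, lmk) {
    flatten_samples(sample_parts(img, lmk, model$s0, N_s))
  }, images, landmarks, SIMPLIFY = FALSE)
  C <- length(vecs[[1L]]) / (model$u * N_s^2)
  X <- do.call(rbind, vecs)
  fit <- pca_fit(X, m)
  new_appearance_model(fit$mean, fit$basis, fit$eigenvalues,
                       layout = list(kind = "parts", u = model$u, N_s = as.integer(N_s)),
                       C = as.integer(C))
}

#' Evaluate an appearance model instance
#'
#' Returns `A0 + A c`.
#'
#' @param model an `appearance_model`.
#' @param c coefficient vector of length `model$m`.
#' @return appearance sample vector.
#' @export
appearance_instance <- function(model, c) {
  if (length(c) != model$m) stop(sprintf("c must have length %d", model$m), call. = FALSE)
  drop(model$A0 + model$A %*% c)
}

# Gradients of one appearance vector under the model's layout, per channel:
# holistic -> central differences inside the mask; parts -> central
# differences inside each patch (one-sided at patch borders). Returns
# list(gx, gy), each a vector aligned with the appearance vector.
appearance_gradients <- function(model, v) {
  C <- model$C
  vals <- unflatten_samples(v, C)  # N x C
  gx <- gy <- matrix(0, nrow(vals), C)
  if (model$layout$kind == "holistic") {
    frame <- model$layout$frame
    for (ch in seq_len(C)) {
      g <- mask_gradients(frame, vals[, ch])
      gx[, ch] <- g$gx; gy[, ch] <- g$gy
    }
  } else {
    N_s <- model$layout$N_s
    u <- model$layout$u
    Np <- N_s^2
    grad1d <- function(M, along) {
      # M is N_s x N_s (rows = y, cols = x); central differences, one-sided edges
      G <- matrix(0, N_s, N_s)
      if (N_s == 1L) return(G)
      if (along == "x") {
        G[, 2:(N_s - 1)] <- (M[, 3:N_s, drop = FALSE] - M[, 1:(N_s - 2), drop = FALSE]) / 2
        G[, 1L] <- M[, 2L] - M[, 1L]
        G[, N_s] <- M[, N_s] - M[, N_s - 1L]
      } else {
        G[2:(N_s - 1), ] <- (M[3:N_s, , drop = FALSE] - M[1:(N_s - 2), , drop = FALSE]) / 2
        G[1L, ] <- M[2L, ] - M[1L, ]
        G[N_s, ] <- M[N_s, ] - M[N_s - 1L, ]
      }
      G
    }
    for (k in seq_len(u)) {
      rows <- (k - 1L) * Np + seq_len(Np)
      for (ch in seq_len(C)) {
        # within-patch row-major: index j = dy * N_s + dx -> matrix byrow
        M <- matrix(vals[rows, ch], N_s, N_s, byrow = TRUE)
        gx[rows, ch] <- as.vector(t(grad1d(M, "x")))
        gy[rows, ch] <- as.vector(t(grad1d(M, "y")))
      }
    }
  }
  list(gx = flatten_samples(gx), gy = flatten_samples(gy))
}

# Row k (per channel) of the steepest-descent image of appearance vector v:
# [grad_x, grad_y] %*% dW/dp at pixel k. `jac` is a warp_jacobian (holistic)
# or the list of per-landmark 2 x n translational Jacobians (parts).
steepest_descent_of <- function(model, v, jac) {
  g <- appearance_gradients(model, v)
  C <- model$C
  if (inherits(jac, "warp_jacobian")) {
    n <- jac$n
    # expand per-pixel Jacobian rows to the N*C layout
    rep_idx <- rep(seq_len(jac$N), each = C)
    g$gx * jac$Jx[rep_idx, , drop = FALSE] + g$gy * jac$Jy[rep_idx, , drop = FALSE]
  } else {
    n <- ncol(jac[[1L]])
    u <- model$layout$u
    Np <- model$layout$N_s^2
    J <- matrix(0, length(v), n)
    for (k in seq_len(u)) {
      rows <- (k - 1L) * Np * C + seq_len(Np * C)
      J[rows, ] <- g$gx[rows] %o% jac[[k]][1L, ] + g$gy[rows] %o% jac[[k]][2L, ]
    }
    J
  }
}

#' Steepest-descent images of an appearance model
#'
#' Computes `J_0` (for the mean appearance) and `J_i`, i = 1..m (one per
#' appearance basis column): row k of each is the appearance gradient at
#' sample k times the 2 x n motion-model Jacobian at that sample. The
#' combined Jacobian at appearance coefficients `c` is
#' `J(c) = J_0 + sum_i c_i J_i`.
#'
#' @param model an `appearance_model`.
#' @param jac a `warp_jacobian` (holistic layout) or the list returned by
#'   [translational_shape_jacobian()] (parts layout).
#' @return object of class `sds_set`: list with `J0` (NC x n) and `Ji`
#'   (list of m NC x n matrices).
#' @export
compute_steepest_descent <- function(model, jac) {
  J0 <- steepest_descent_of(model, model$A0, jac)
  Ji <- lapply(seq_len(model$m), function(i) {
    steepest_descent_of(model, model$A[, i], jac)
  })
  structure(list(J0 = J0, Ji = Ji, n = ncol(J0)), class = "sds_set")
}

#' Combined Jacobian J(c) = J_0 + sum_i c_i J_i
#'
#' @param sds an `sds_set`.
#' @param c appearance coefficient vector (length m).
#' @return NC x n matrix.
#' @export
combine_jacobian <- function(sds, c) {
  J <- sds$J0
  for (i in seq_along(c)) if (c[i] != 0) J <- J + c[i] * sds$Ji[[i]]
  J
}

#' Matrix-free orthogonal-complement projector
#'
#' For an orthonormal basis A, represents `P_A = E - A A^T` without ever
#' materializing the N x N matrix: `apply(X) = X - A (A^T X)`, cost
#' O(l m N) for l columns.
#'
#' @param A orthonormal basis (checked to 1e-8).
#' @return object of class `projector` with element `apply`.
#' @export
build_projector <- function(A) {
  if (ncol(A) > 0L) {
    G <- crossprod(A)
    if (max(abs(G - diag(ncol(A)))) > 1e-8) {
      stop("basis is not orthonormal", call. = FALSE)
    }
  }
  ap <- function(X) {
    if (ncol(A) == 0L) return(X)
    X - A %*% crossprod(A, X)
  }
  structure(list(apply = ap, A = A), class = "projector")
}
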