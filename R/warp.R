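# Piecewise-affine warping: sampling an image in the reference frame, the
# warp Jacobian at p = 0, and the first-order inverse-compositional update.

#' Warp an image into the reference frame
#'
#' For each masked reference pixel, maps through the containing triangle's
#' barycentric coordinates to the corresponding point of the source triangle
#' and samples the image by bilinear interpolation (out-of-bounds samples
#' clamp to the nearest border pixel). This is the sampled vector `I[p]` for
#' a source shape `s(p)`.
#'
#' @param image single-channel matrix or H x W x C array, values indexed
#'   `[y + 1, x + 1]` in 0-based pixel coordinates.
#' @param source_shape landmark vector of the shape in the image (same u and
#'   triangulation topology as the frame's mean shape).
#' @param frame a `ref_frame` built from the model mean shape.
#' @return N x C matrix of samples in the frame's canonical (row-major)
#'   pixel order, with attribute `inverted_triangles` listing any source
#'   triangles whose orientation is flipped relative to the reference (a
#'   warning is raised but sampling proceeds; fitting can transiently invert
#'   triangles).
#' @export
warp_image <- function(image, source_shape, frame) {
  src <- lmk_matrix(source_shape)
  if (nrow(src) != nrow(frame$points)) {
    stop("source shape has a different number of landmarks than the frame", call. = FALSE)
  }
  tri <- frame$triangles
  # orientation check: signed area per triangle, reference vs source
  sgn <- function(P) {
    (P[tri[, 2L], 1L] - P[tri[, 1L], 1L]) * (P[tri[, 3L], 2L] - P[tri[, 1L], 2L]) -
      (P[tri[, 3L], 1L] - P[tri[, 1L], 1L]) * (P[tri[, 2L], 2L] - P[tri[, 1L], 2L])
  }
  flipped <- which(sgn(frame$points) * sgn(src) < 0)
  if (length(flipped) > 0L) {
    warning(sprintf("%d inverted triangle(s) during warp", length(flipped)), call. = FALSE)
  }
  v1 <- tri[frame$tri_id, 1L]; v2 <- tri[frame$tri_id, 2L]; v3 <- tri[frame$tri_id, 3L]
  b <- frame$bary
  xs <- b[, 1L] * src[v1, 1L] + b[, 2L] * src[v2, 1L] + b[, 3L] * src[v3, 1L]
  ys <- b[, 1L] * src[v1, 2L] + b[, 2L] * src[v2, 2L] + b[, 3L] * src[v3, 2L]
  out <- sample_channels(image, xs, ys)
  attr(out, "inverted_triangles") <- flipped
  out
}

#' Warp Jacobian of the piecewise-affine motion model at p = 0
#'
#' The derivative of the warped position of each masked pixel with respect to
#' the shape parameters is the barycentric combination of the per-vertex
#' translational shape Jacobians of the containing triangle.
#'
#' @param model a `shape_model` whose mean shape defined `frame`.
#' @param frame a `ref_frame` built from `model$s0`.
#' @return object of class `warp_jacobian`: list with `Jx` and `Jy`
#'   (both N x n), row k holding the x and y derivative rows of pixel k.
#' @export
warp_jacobian <- function(model, frame) {
  S <- model$S
  u <- model$u
  Sx <- S[seq(1L, 2L * u, by = 2L), , drop = FALSE]
  Sy <- S[seq(2L, 2L * u, by = 2L), , drop = FALSE]
  tri <- frame$triangles
  v1 <- tri[frame$tri_id, 1L]; v2 <- tri[frame$tri_id, 2L]; v3 <- tri[frame$tri_id, 3L]
  b <- frame$bary
  Jx <- b[, 1L] * Sx[v1, , drop = FALSE] + b[, 2L] * Sx[v2, , drop = FALSE] +
    b[, 3L] * Sx[v3, , drop = FALSE]
  Jy <- b[, 1L] * Sy[v1, , drop = FALSE] + b[, 2L] * Sy[v2, , drop = FALSE] +
    b[, 3L] * Sy[v3, , drop = FALSE]
  structure(list(Jx = Jx, Jy = Jy, n = ncol(S), N = frame$N), class = "warp_jacobian")
}

# Affine map of each triangle from the reference shape to a target shape,
# applied to arbitrary points attached to triangle `t`.
map_through_triangle <- function(ref_pts, tgt_pts, tri_row, px, py) {
  a <- ref_pts[tri_row[1L], ]; b <- ref_pts[tri_row[2L], ]; c <- ref_pts[tri_row[3L], ]
  bc <- barycentric_coords(a, b, c, px, py)
  A <- tgt_pts[tri_row[1L], ]; B <- tgt_pts[tri_row[2L], ]; C <- tgt_pts[tri_row[3L], ]
  cbind(bc[, 1L] * A[1L] + bc[, 2L] * B[1L] + bc[, 3L] * C[1L],
        bc[, 1L] * A[2L] + bc[, 2L] * B[2L] + bc[, 3L] * C[2L])
}

#' Inverse-compositional parameter update
#'
#' Composes the inverse of the incremental warp `dp` with the current warp.
#' In `translational` mode (the part-based motion model) composition reduces
#' exactly to addition, so the update is `p - dp`. In `piecewise_affine`
#' mode a first-order approximation is used: the mean shape is displaced by
#' `-S dp`, each displaced vertex is mapped through the current warp
#' (averaging the affine maps of the triangles sharing that vertex), and the
#' resulting landmark set is projected back onto the shape model.
#'
#' @param p current parameter vector (length n).
#' @param dp incremental parameter vector (length n).
#' @param model the `shape_model`.
#' @param mode `"piecewise_affine"` or `"translational"`.
#' @param frame the `ref_frame` (required for piecewise-affine mode).
#' @return updated parameter vector.
#' @export
inverse_compositional_update <- function(p, dp, model,
                                         mode = c("piecewise_affine", "translational"),
                                         frame = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(p) == model$n, length(dp) == model$n,
            all(is.finite(p)), all(is.finite(dp)))
  if (mode == "translational") return(p - dp)
  if (is.null(frame)) stop("piecewise-affine mode needs the reference frame", call. = FALSE)

  disp <- lmk_matrix(drop(model$s0 - model$S %*% dp))
  ref <- frame$points
  cur <- lmk_matrix(shape_instance(model, p))
  tri <- frame$triangles
  u <- model$u
  newpts <- matrix(0, u, 2L)
  for (k in seq_len(u)) {
    rows <- which(tri[, 1L] == k | tri[, 2L] == k | tri[, 3L] == k)
    acc <- c(0, 0)
    for (t in rows) {
      acc <- acc + map_through_triangle(ref, cur, tri[t, ], disp[k, 1L], disp[k, 2L])[1L, ]
    }
    newpts[k, ] <- acc / length(rows)
  }
  drop(project_shape(model, lmk_vector(newpts)))
}
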