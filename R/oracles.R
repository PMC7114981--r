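# Brute-force reference solvers. Deliberately naive (dense projectors,
# stacked pseudo-inverse solves) and size-guarded: they exist to
# cross-check the fast matrix-free implementations on small fixtures, never
# to fit models.

oracle_guard <- function(N, nm) {
  if (N > 500L) stop("oracle refuses N > 500", call. = FALSE)
  if (nm > 30L) stop("oracle refuses m + n > 30", call. = FALSE)
}

#' Dense orthogonal-complement projector (oracle)
#'
#' Materializes `E - A A^T`.
#'
#' @param A orthonormal basis (N <= 500 rows).
#' @return N x N matrix.
#' @export
oracle_projector <- function(A) {
  oracle_guard(nrow(A), ncol(A))
  diag(nrow(A)) - tcrossprod(A)
}

#' Dense extended projector (oracle)
#'
#' Materializes `E - B (B^T B)^+ B^T` via the pseudo-inverse, for a possibly
#' non-orthonormal, possibly rank-deficient basis B.
#'
#' @param B basis matrix (N <= 500 rows).
#' @return N x N matrix.
#' @export
oracle_extended_projector <- function(B) {
  oracle_guard(nrow(B), min(30L, ncol(B)))
  sv <- svd(B)
  pos <- sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10
  Ginv <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
  diag(nrow(B)) - B %*% Ginv
}

#' Stacked pseudo-inverse solve of the simultaneous linearized problem
#' (oracle)
#'
#' Minimizes `||r - A dc - J dp||` over `(dc, dp)` by one pseudo-inverse of
#' the stacked matrix `[A J]`.
#'
#' @param residual residual vector.
#' @param A appearance basis.
#' @param J combined Jacobian.
#' @return list with `dp`, `dc`.
#' @export
oracle_sic_solve <- function(residual, A, J) {
  oracle_guard(nrow(J), ncol(A) + ncol(J))
  X <- cbind(A, J)
  sv <- svd(X)
  pos <- sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10
  sol <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], residual)) / sv$d[pos])
  m <- ncol(A)
  list(dc = drop(sol)[seq_len(m)], dp = drop(sol)[-seq_len(m)])
}

#' Schur-complement elimination of the appearance block (oracle)
#'
#' Solves the dense normal equations of the simultaneous problem and
#' eliminates `dc`, returning the shape step alone.
#'
#' @inheritParams oracle_sic_solve
#' @return `dp` vector.
#' @export
oracle_schur_dp <- function(residual, A, J) {
  oracle_guard(nrow(J), ncol(A) + ncol(J))
  AtA <- crossprod(A); AtJ <- crossprod(A, J); JtJ <- crossprod(J)
  S <- JtJ - t(AtJ) %*% solve(AtA, AtJ)
  rhs <- crossprod(J, residual) - t(AtJ) %*% solve(AtA, crossprod(A, residual))
  drop(solve(S, rhs))
}

#' Explicit diagonal-matrix weighted solve (oracle)
#'
#' Materializes the binary diagonal weight matrix `W` and solves the
#' weighted simultaneous problem `min ||W^(1/2) (r - A dc - J dp)||`
#' densely.
#'
#' @param residual residual vector.
#' @param A appearance basis.
#' @param J combined Jacobian.
#' @param keep logical vector of kept positions.
#' @return list with `dp`, `dc`.
#' @export
oracle_weighted_solve <- function(residual, A, J, keep) {
  oracle_guard(nrow(J), ncol(A) + ncol(J))
  W <- diag(as.numeric(keep))
  X <- W %*% cbind(A, J)
  sv <- svd(X)
  pos <- sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10
  sol <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], W %*% residual)) / sv$d[pos])
  m <- ncol(A)
  list(dc = drop(sol)[seq_len(m)], dp = drop(sol)[-seq_len(m)])
}

#' Point-in-polygon scan (oracle)
#'
#' Ray-casting test of integer grid pixels against a polygon, independent of
#' the triangulation-based mask construction.
#'
#' @param poly polygon vertices (k x 2, in order).
#' @param xs,ys integer coordinate grids to test.
#' @return logical matrix/vector: inside (or on the boundary, within 1e-9).
#' @export
oracle_point_in_polygon <- function(poly, xs, ys) {
  k <- nrow(poly)
  inside <- rep(FALSE, length(xs))
  on_edge <- rep(FALSE, length(xs))
  j <- k
  for (i in seq_len(k)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # boundary check: point on segment
    ex <- xj - xi; ey <- yj - yi
    t <- ((xs - xi) * ex + (ys - yi) * ey) / (ex^2 + ey^2)
    t <- clamp(t, 0, 1)
    d2 <- (xs - (xi + t * ex))^2 + (ys - (yi + t * ey))^2
    on_edge <- on_edge | d2 < 1e-18
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}
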