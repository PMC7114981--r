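# Delaunay triangulation (Bowyer-Watson). Written in-package: the landmark
# counts involved are tiny (tens of points) so an O(u^2) incremental insert
# is ample, and the triangulation is computed once at training time and
# frozen into the model container.

tri_circumcircle <- function(a, b, c) {
  ax <- a[1L]; ay <- a[2L]; bx <- b[1L]; by <- b[2L]; cx <- c[1L]; cy <- c[2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.eps * 100 * max(abs(c(ax, ay, bx, by, cx, cy)), 1)^2) {
    return(NULL)  # collinear
  }
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)  # center and squared radius
}

#' Delaunay triangulation of a 2-D point set
#'
#' Incremental Bowyer-Watson triangulation. Cocircular ties (e.g. the four
#' corners of a square) are resolved deterministically by the insertion
#' order, and the triangle list is canonicalized (vertex indices sorted
#' ascending within a triangle, triangles sorted lexicographically) so the
#' output is reproducible.
#'
#' @param pts u x 2 matrix of point coordinates.
#' @return integer matrix with one row per triangle and 3 vertex-index
#'   columns (1-based).
#' @export
delaunay_triangulate <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2L)
  u <- nrow(pts)
  if (u < 3L) stop("need at least 3 points", call. = FALSE)
  rng <- apply(pts, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ], 1)
  # collinearity check via maximal triangle area
  base <- pts[1L, ]
  vecs <- sweep(pts, 2L, base)
  areas <- abs(outer(vecs[, 1L], vecs[, 2L]) - outer(vecs[, 2L], vecs[, 1L]))
  if (max(areas) < 1e-9 * span^2) stop("points are collinear", call. = FALSE)

  mid <- colMeans(rng)
  M <- 20 * span
  sp <- rbind(
    c(mid[1L] - 2 * M, mid[2L] - M),
    c(mid[1L] + 2 * M, mid[2L] - M),
    c(mid[1L], mid[2L] + 2 * M)
  )
  P <- rbind(pts, sp)
  tris <- list(c(u + 1L, u + 2L, u + 3L))
  circ <- list(tri_circumcircle(sp[1L, ], sp[2L, ], sp[3L, ]))
  eps <- 1e-9 * span^2

  for (i in seq_len(u)) {
    p <- pts[i, ]
    bad <- vapply(circ, function(cc) {
      !is.null(cc) && ((p[1L] - cc[1L])^2 + (p[2L] - cc[2L])^2 < cc[3L] - eps)
    }, logical(1))
    bad_tris <- tris[bad]
    # boundary edges: edges of bad triangles appearing exactly once
    edges <- do.call(rbind, lapply(bad_tris, function(t) {
      rbind(sort(t[c(1L, 2L)]), sort(t[c(2L, 3L)]), sort(t[c(1L, 3L)]))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    keep <- key %in% names(which(table(key) == 1L))
    poly <- edges[keep, , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (e in seq_len(nrow(poly))) {
      t <- c(poly[e, 1L], poly[e, 2L], i)
      cc <- tri_circumcircle(P[t[1L], ], P[t[2L], ], P[t[3L], ])
      if (is.null(cc)) next
      tris[[length(tris) + 1L]] <- t
      circ[[length(circ) + 1L]] <- cc
    }
  }
  keep <- vapply(tris, function(t) all(t <= u), logical(1))
  tri <- do.call(rbind, tris[keep])
  tri <- t(apply(tri, 1L, sort))
  tri <- tri[do.call(order, as.data.frame(tri)), , drop = FALSE]
  storage.mode(tri) <- "integer"
  dimnames(tri) <- NULL
  tri
}
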