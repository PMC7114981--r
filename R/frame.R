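# Reference frame of the mean shape: pixel mask inside the convex hull,
# triangulation, and per-pixel barycentric coordinates.

# Barycentric coordinates of points (px, py) with respect to triangle
# (a, b, c); returns a 3-column matrix (alpha, beta, gamma).
barycentric_coords <- function(a, b, c, px, py) {
  d <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (c[1L] - a[1L]) * (b[2L] - a[2L])
  vx <- px - a[1L]; vy <- py - a[2L]
  beta <- (vx * (c[2L] - a[2L]) - (c[1L] - a[1L]) * vy) / d
  gamma <- ((b[1L] - a[1L]) * vy - vx * (b[2L] - a[2L])) / d
  cbind(1 - beta - gamma, beta, gamma)
}

#' Build the reference frame of a mean shape
#'
#' Delaunay-triangulates the mean shape and collects every pixel (integer
#' coordinate pair, pixel centers at integers) whose center lies inside the
#' convex hull, together with the containing triangle and its barycentric
#' coordinates. Boundary ties are broken by the lowest triangle index. The
#' mask is ordered row-major (by y, then x).
#'
#' @param s0 mean-shape landmark vector in pixel units (length 2u).
#' @param triangles optional precomputed triangulation (rows of vertex
#'   indices); computed by [delaunay_triangulate()] when omitted. Supplying
#'   the stored triangulation keeps the topology frozen across uses.
#' @return object of class `ref_frame`: list with `points` (u x 2 matrix),
#'   `triangles`, `mask` (N x 2 integer pixel coordinates), `bary` (N x 3),
#'   `tri_id` (length N), `N`, `nb` (N x 4 neighbor row indices, NA outside
#'   the mask: -x, +x, -y, +y), and the bounding box.
#' @export
build_reference_frame <- function(s0, triangles = NULL) {
  pts <- lmk_matrix(s0)
  tri <- if (is.null(triangles)) delaunay_triangulate(pts) else triangles
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  xs <- seq.int(ceiling(xr[1L] - 1e-9), floor(xr[2L] + 1e-9))
  ys <- seq.int(ceiling(yr[1L] - 1e-9), floor(yr[2L] + 1e-9))
  if (length(xs) == 0L || length(ys) == 0L) stop("mean shape hull contains no pixels", call. = FALSE)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))

  tol <- 1e-12
  tri_id <- rep(NA_integer_, length(px))
  bary <- matrix(NA_real_, length(px), 3L)
  for (t in seq_len(nrow(tri))) {
    todo <- which(is.na(tri_id))
    if (length(todo) == 0L) break
    a <- pts[tri[t, 1L], ]; b <- pts[tri[t, 2L], ]; c <- pts[tri[t, 3L], ]
    bc <- barycentric_coords(a, b, c, px[todo], py[todo])
    inside <- bc[, 1L] >= -tol & bc[, 2L] >= -tol & bc[, 3L] >= -tol
    hit <- todo[inside]
    tri_id[hit] <- t
    bary[hit, ] <- bc[inside, , drop = FALSE]
  }
  keep <- which(!is.na(tri_id))
  if (length(keep) == 0L) stop("mean shape hull contains no pixels", call. = FALSE)
  mask <- cbind(x = px[keep], y = py[keep])
  ord <- order(mask[, 2L], mask[, 1L])  # row-major: y then x
  mask <- mask[ord, , drop = FALSE]
  bary <- bary[keep, , drop = FALSE][ord, , drop = FALSE]
  tri_id <- tri_id[keep][ord]
  N <- nrow(mask)

  # raster index for neighbor lookups (gradients)
  x0 <- min(mask[, 1L]); y0 <- min(mask[, 2L])
  W <- max(mask[, 1L]) - x0 + 1L; H <- max(mask[, 2L]) - y0 + 1L
  idx <- matrix(NA_integer_, H, W)
  idx[cbind(mask[, 2L] - y0 + 1L, mask[, 1L] - x0 + 1L)] <- seq_len(N)
  at <- function(x, y) {
    r <- y - y0 + 1L; cl <- x - x0 + 1L
    ok <- r >= 1L & r <= H & cl >= 1L & cl <= W
    out <- rep(NA_integer_, length(x))
    out[ok] <- idx[cbind(r[ok], cl[ok])]
    out
  }
  nb <- cbind(
    xm = at(mask[, 1L] - 1L, mask[, 2L]),
    xp = at(mask[, 1L] + 1L, mask[, 2L]),
    ym = at(mask[, 1L], mask[, 2L] - 1L),
    yp = at(mask[, 1L], mask[, 2L] + 1L)
  )

  structure(list(
    points = pts, s0 = lmk_vector(pts), triangles = tri,
    mask = mask, bary = bary, tri_id = tri_id, N = N, nb = nb,
    bbox = c(xmin = x0, ymin = y0, xmax = max(mask[, 1L]), ymax = max(mask[, 2L]))
  ), class = "ref_frame")
}

# Gradients of a per-mask-pixel value vector: central differences inside the
# mask, one-sided at boundaries, zero where no neighbor exists.
mask_gradients <- function(frame, v) {
  nb <- frame$nb
  gx <- gy <- numeric(frame$N)
  grad1 <- function(vm, vp, v0) {
    has_m <- !is.na(vm); has_p <- !is.na(vp)
    g <- numeric(length(v0))
    both <- has_m & has_p
    g[both] <- (vp[both] - vm[both]) / 2
    onlym <- has_m & !has_p
    g[onlym] <- v0[onlym] - vm[onlym]
    onlyp <- has_p & !has_m
    g[onlyp] <- vp[onlyp] - v0[onlyp]
    g
  }
  vm <- v[nb[, "xm"]]; vp <- v[nb[, "xp"]]
  gx <- grad1(vm, vp, v)
  vm <- v[nb[, "ym"]]; vp <- v[nb[, "yp"]]
  gy <- grad1(vm, vp, v)
  list(gx = gx, gy = gy)
}

# Paint a per-mask-pixel value vector into a dense raster covering the
# frame bounding box; pixels outside the mask take `fill` (default: mean of
# the values). Returns list(img, x0, y0) with 0-based raster origin.
frame_raster <- function(frame, v, fill = NULL) {
  if (is.null(fill)) fill <- mean(v)
  x0 <- frame$bbox[["xmin"]]; y0 <- frame$bbox[["ymin"]]
  W <- frame$bbox[["xmax"]] - x0 + 1L; H <- frame$bbox[["ymax"]] - y0 + 1L
  img <- matrix(fill, H, W)
  img[cbind(frame$mask[, 2L] - y0 + 1L, frame$mask[, 1L] - x0 + 1L)] <- v
  list(img = img, x0 = x0, y0 = y0)
}
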