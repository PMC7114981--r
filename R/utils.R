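# Internal helpers shared across modules.

#' Convert an interleaved landmark vector to a u x 2 matrix
#'
#' Landmark sets are stored as interleaved vectors `[x1, y1, ..., xu, yu]`
#' in 0-based pixel coordinates (x rightward, y downward).
#'
#' @param v numeric vector of length 2u.
#' @return u x 2 matrix with columns x, y.
#' @export
lmk_matrix <- function(v) {
  check_landmarks(v)
  matrix(v, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' Convert a u x 2 landmark matrix to the interleaved vector form
#'
#' @param m u x 2 matrix with columns x, y.
#' @return numeric vector `[x1, y1, ..., xu, yu]`.
#' @export
lmk_vector <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 2L)
  as.vector(t(m))
}

check_landmarks <- function(v, u = NULL) {
  if (!is.numeric(v) || length(v) %% 2L != 0L) {
    stop("landmark set must be a numeric vector of even length", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("landmark coordinates must be finite", call. = FALSE)
  if (length(v) < 6L) stop("landmark set needs at least 3 points", call. = FALSE)
  if (!is.null(u) && length(v) != 2L * u) {
    stop(sprintf("expected %d landmarks, got %d", u, length(v) / 2L), call. = FALSE)
  }
  invisible(v)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear sampling of a single-channel image at 0-based coordinates.
# Out-of-bounds coordinates are clamped to the border pixel.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 0, w - 1)
  y <- clamp(y, 0, h - 1)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Sample all channels of an image (matrix or H x W x C array) at 0-based
# coordinates; returns a length(x) x C matrix.
sample_channels <- function(img, x, y) {
  if (is.matrix(img)) {
    return(matrix(bilinear_sample(img, x, y), ncol = 1L))
  }
  stopifnot(length(dim(img)) == 3L)
  C <- dim(img)[3L]
  out <- matrix(0, length(x), C)
  for (ch in seq_len(C)) out[, ch] <- bilinear_sample(img[, , ch], x, y)
  out
}

# Flatten an N x C sample matrix into the canonical appearance vector:
# channel-major within pixel (pixel k's C values are contiguous).
flatten_samples <- function(samples) {
  as.vector(t(samples))
}

# Inverse of flatten_samples.
unflatten_samples <- function(v, C) {
  matrix(v, ncol = C, byrow = TRUE)
}

# Force the largest-magnitude entry of each column to be positive so that
# serialized bases are reproducible across platforms.
canonical_sign <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

# Linear solve guarded by a ridge fallback for near-singular PSD systems.
# Returns the solution with attributes `rcond` and `ridged`.
solve_psd <- function(H, b, ridge_tol = 1e-12) {
  H <- (H + t(H)) / 2
  if (nrow(H) == 0L) {
    out <- matrix(0, 0L, NCOL(b))
    attr(out, "rcond") <- 1; attr(out, "ridged") <- FALSE
    return(out)
  }
  rc <- tryCatch(rcond(H), error = function(e) 0)
  ridged <- FALSE
  if (!is.finite(rc) || rc < ridge_tol) {
    ridge <- 1e-8 * sum(diag(H)) / nrow(H)
    if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
    H <- H + diag(ridge, nrow(H))
    ridged <- TRUE
    warning("near-singular Hessian: ridge fallback applied", call. = FALSE)
  }
  out <- solve(H, b)
  attr(out, "rcond") <- rc
  attr(out, "ridged") <- ridged
  out
}

# 2x2 average-pool-free bilinear resize used by the image pyramid.
# `sc` < 1 shrinks; landmark coordinates scale as l * sc.
resize_image <- function(img, sc) {
  if (sc == 1) return(img)
  dims <- dim(img)
  h <- dims[1L]; w <- dims[2L]
  nh <- max(2L, floor(h * sc)); nw <- max(2L, floor(w * sc))
  xg <- (seq_len(nw) - 1) / sc
  yg <- (seq_len(nh) - 1) / sc
  xs <- rep(xg, each = nh)
  ys <- rep(yg, times = nw)
  if (is.matrix(img)) {
    matrix(bilinear_sample(img, xs, ys), nh, nw)
  } else {
    C <- dims[3L]
    out <- array(0, c(nh, nw, C))
    for (ch in seq_len(C)) {
      out[, , ch] <- matrix(bilinear_sample(img[, , ch], xs, ys), nh, nw)
    }
    out
  }
}
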