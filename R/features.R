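# Dense per-pixel gradient-orientation descriptors: an N_f-channel feature
# image in the spirit of densely-sampled SIFT, reduced to a single spatial
# scale so the per-pixel dimension is exactly N_f.

# Separable Gaussian smoothing with zero padding.
gaussian_blur <- function(img, sigma, radius) {
  k <- exp(-(seq.int(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- function(M, r, dim) {
    if (dim == 1L) rbind(matrix(0, r, ncol(M)), M, matrix(0, r, ncol(M)))
    else cbind(matrix(0, nrow(M), r), M, matrix(0, nrow(M), r))
  }
  Mp <- pad(img, radius, 1L)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * Mp[seq_len(h) + i - 1L, , drop = FALSE]
  Mp <- pad(out, radius, 2L)
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) out2 <- out2 + k[i] * Mp[, seq_len(w) + i - 1L, drop = FALSE]
  out2
}

#' Dense gradient-orientation descriptor image
#'
#' At every pixel, computes a soft histogram of gradient orientations over
#' `N_f` bins covering [0, 2*pi): each pixel's gradient magnitude is split
#' linearly between the two nearest orientation bins, the per-bin vote
#' images are Gaussian-weighted over a `cell_size` window, and the resulting
#' per-pixel descriptor is contrast-normalized (unit length, clipped at 0.2,
#' renormalized; an all-zero descriptor stays zero). Deterministic for fixed
#' inputs; rotating the input by 90 degrees permutes the orientation
#' channels by N_f/4 positions for interior pixels.
#'
#' @param image single-channel matrix.
#' @param N_f number of orientation channels, 4 or 8 (default 8).
#' @param cell_size spatial pooling window in pixels (>= 3, default 8);
#'   the Gaussian has sd `cell_size / 2` and radius `cell_size`.
#' @return H x W x N_f array of non-negative channel values.
#' @export
dense_descriptor <- function(image, N_f = 8L, cell_size = 8L) {
  if (!is.matrix(image)) stop("input must be a single-channel matrix", call. = FALSE)
  if (!N_f %in% c(4L, 8L)) stop("N_f must be 4 or 8", call. = FALSE)
  if (cell_size < 3L) stop("cell_size must be at least 3", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  gx <- gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (image[, 3:w, drop = FALSE] - image[, 1:(w - 2), drop = FALSE]) / 2
  gx[, 1L] <- image[, 2L] - image[, 1L]
  gx[, w] <- image[, w] - image[, w - 1L]
  gy[2:(h - 1), ] <- (image[3:h, , drop = FALSE] - image[1:(h - 2), , drop = FALSE]) / 2
  gy[1L, ] <- image[2L, ] - image[1L, ]
  gy[h, ] <- image[h, ] - image[h - 1L, ]

  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  binw <- 2 * pi / N_f
  b <- ang / binw                      # fractional bin position
  b0 <- floor(b) %% N_f
  frac <- b - floor(b)
  votes <- array(0, c(h, w, N_f))
  for (k in 0:(N_f - 1L)) {
    v0 <- mag * (1 - frac) * (b0 == k)
    v1 <- mag * frac * (((b0 + 1L) %% N_f) == k)
    votes[, , k + 1L] <- v0 + v1
  }
  sigma <- cell_size / 2
  radius <- as.integer(cell_size)
  for (k in seq_len(N_f)) votes[, , k] <- gaussian_blur(votes[, , k], sigma, radius)

  # per-pixel contrast normalization with clipping
  nrm <- sqrt(apply(votes^2, c(1L, 2L), sum))
  nz <- nrm > 0
  for (k in seq_len(N_f)) {
    v <- votes[, , k]
    v[nz] <- v[nz] / nrm[nz]
    votes[, , k] <- v
  }
  votes <- pmin(votes, 0.2)
  nrm2 <- sqrt(apply(votes^2, c(1L, 2L), sum))
  nz <- nrm2 > 0
  for (k in seq_len(N_f)) {
    v <- votes[, , k]
    v[nz] <- v[nz] / nrm2[nz]
    votes[, , k] <- v
  }
  votes
}
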