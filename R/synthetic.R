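# Synthetic world generator: ground-truth shape/appearance models built from
# smooth low-order trigonometric fields, instance rendering with known
# parameters, and the initialization perturbation protocols.

#' Generate a synthetic ground-truth model world
#'
#' Builds a fully known shape-and-appearance model: the mean shape is a
#' landmark ring (ellipse) plus interior points; the deformation basis is
#' drawn from low-order trigonometric displacement fields (so warps stay
#' non-degenerate at 3-sigma parameter draws) orthonormalized against the 4
#' similarity bases; the appearance mean and basis are smooth band-limited
#' textures on the reference mask, orthonormalized. Everything is a
#' deterministic function of `(u, n, m, image_size, seed)`.
#'
#' @param u landmark count (>= 4).
#' @param n number of deformation (non-similarity) shape modes (>= 1).
#' @param m number of appearance modes (>= 0).
#' @param image_size canvas side in pixels.
#' @param seed RNG seed.
#' @return object of class `synthetic_world`: list with `shape`
#'   (a `shape_model` with n + 4 columns), `frame`, `app`
#'   (an `appearance_model`), `config`.
#' @export
make_world <- function(u = 20L, n = 6L, m = 12L, image_size = 96L, seed = 1L) {
  if (u < 4L || n < 1L || m < 0L) stop("infeasible dimensions", call. = FALSE)
  if (n + 4L > 2L * u) stop(sprintf("n + 4 = %d exceeds 2u = %d", n + 4L, 2L * u), call. = FALSE)
  set.seed(seed)
  ctr <- image_size / 2
  radius <- 0.28 * image_size
  n_int <- max(1L, round(u / 5))
  n_ring <- u - n_int
  th <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  ring <- cbind(ctr + radius * cos(th), ctr + 0.92 * radius * sin(th))
  thi <- 2 * pi * (seq_len(n_int) - 1L) / n_int + pi / n_int
  interior <- cbind(ctr + 0.45 * radius * cos(thi), ctr + 0.4 * radius * sin(thi))
  pts <- rbind(ring, interior)
  s0 <- lmk_vector(pts)

  # polar coordinates of every landmark relative to the center
  ang <- atan2(pts[, 2L] - ctr, pts[, 1L] - ctr)
  rad <- sqrt(rowSums(sweep(pts, 2L, c(ctr, ctr))^2)) / radius

  sim <- similarity_basis(s0)
  basis <- sim
  defm <- matrix(0, 2L * u, n)
  for (j in seq_len(n)) {
    for (attempt in 1:20) {
      co <- stats::rnorm(12L)
      fld <- function(a) {
        co[a] * cos(ang) + co[a + 1L] * sin(ang) +
          co[a + 2L] * cos(2 * ang) + co[a + 3L] * sin(2 * ang) +
          co[a + 4L] * cos(3 * ang) + co[a + 5L] * sin(3 * ang)
      }
      dx <- rad * fld(1L)
      dy <- rad * fld(7L)
      v <- lmk_vector(cbind(dx, dy))
      v <- v - basis %*% crossprod(basis, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-6) { defm[, j] <- v / nv; basis <- cbind(basis, defm[, j]); break }
      if (attempt == 20L) stop("could not draw an independent deformation field", call. = FALSE)
    }
  }
  S <- canonical_sign(cbind(sim, defm))
  ev_sim <- rep((0.02 * image_size)^2, 4L)
  ev_def <- (0.08 * radius / seq_len(n)^0.7)^2
  shape <- shape_model_from_basis(s0, S, c(ev_sim, ev_def))

  frame <- build_reference_frame(s0)
  tx <- (frame$mask[, 1L] - frame$bbox[["xmin"]]) / max(1L, frame$bbox[["xmax"]] - frame$bbox[["xmin"]])
  ty <- (frame$mask[, 2L] - frame$bbox[["ymin"]]) / max(1L, frame$bbox[["ymax"]] - frame$bbox[["ymin"]])
  field <- function(n_waves, max_freq, amp) {
    v <- numeric(frame$N)
    for (h in seq_len(n_waves)) {
      fx <- sample.int(max_freq, 1L); fy <- sample.int(max_freq, 1L)
      v <- v + stats::rnorm(1L, sd = amp / h) * cos(2 * pi * (fx * tx + fy * ty) + stats::runif(1L, 0, 2 * pi))
    }
    v
  }
  A0 <- 0.55 + field(5L, 3L, 0.15)
  if (m > 0L) {
    raw <- vapply(seq_len(m), function(i) field(6L, 4L, 0.08), numeric(frame$N))
    qa <- qr(raw)
    if (qa$rank < m) stop("appearance fields are rank-deficient", call. = FALSE)
    A <- canonical_sign(qr.Q(qa)[, seq_len(m), drop = FALSE])
  } else {
    A <- matrix(0, frame$N, 0L)
  }
  ev_app <- if (m > 0L) (1.5 / sqrt(seq_len(m)))^2 else numeric(0)
  app <- new_appearance_model(A0, A, ev_app,
                              layout = list(kind = "holistic", frame = frame), C = 1L)

  structure(list(
    shape = shape, frame = frame, app = app,
    config = list(u = u, n = n, m = m, image_size = image_size, seed = seed,
                  radius = radius, center = ctr)
  ), class = "synthetic_world")
}

#' Draw random in-model parameters for a synthetic world
#'
#' Deformation and appearance coefficients are Gaussian with the world's
#' eigenvalue variances, truncated at 3 sigma (keeping warps non-degenerate);
#' similarity coefficients are drawn at half scale. Uses the ambient RNG.
#'
#' @param world a `synthetic_world`.
#' @return list with `p` (length n + 4) and `c` (length m).
#' @export
draw_parameters <- function(world) {
  sds <- sqrt(world$shape$eigenvalues)
  p <- stats::rnorm(length(sds)) * sds
  p[seq_len(4L)] <- p[seq_len(4L)] * 0.5
  p <- clamp(p, -3 * sds, 3 * sds)
  csd <- sqrt(world$app$eigenvalues)
  cc <- clamp(stats::rnorm(length(csd)) * csd, -3 * csd, 3 * csd)
  list(p = p, c = cc)
}

#' Render a synthetic model instance onto an image canvas
#'
#' Synthesizes the appearance `A0 + A c` in the reference frame, warps it to
#' the shape `s(p)` by inverse warping each canvas pixel inside the warped
#' hull (sampling the reference texture bilinearly), fills the background
#' with the mean texture value, and adds i.i.d. Gaussian noise.
#'
#' @param world a `synthetic_world`.
#' @param p shape parameters (length n + 4, within 3 sigma of the world's
#'   eigenvalues).
#' @param c appearance coefficients (length m).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   (intensity units; default 0).
#' @return list with `image` (image_size x image_size matrix) and
#'   `landmarks` (ground-truth landmark vector, exactly `s(p)`).
#' @export
render_instance <- function(world, p, c = rep(0, world$app$m), noise_sd = 0) {
  sds <- sqrt(world$shape$eigenvalues)
  if (any(abs(p) > 3 * sds + 1e-9)) {
    stop("shape parameters exceed the 3-sigma bound", call. = FALSE)
  }
  lmk <- shape_instance(world$shape, p)
  sz <- world$config$image_size
  M <- lmk_matrix(lmk)
  if (any(M < 1) || any(M > sz - 2)) {
    stop("instance lies off the canvas", call. = FALSE)
  }
  tex <- appearance_instance(world$app, c)
  ras <- frame_raster(world$frame, tex)
  bg <- mean(tex)

  img <- matrix(bg, sz, sz)
  tri <- world$frame$triangles
  ref <- world$frame$points
  px <- rep(0:(sz - 1L), times = sz)
  py <- rep(0:(sz - 1L), each = sz)
  assigned <- rep(FALSE, length(px))
  for (t in seq_len(nrow(tri))) {
    todo <- which(!assigned)
    if (length(todo) == 0L) break
    a <- M[tri[t, 1L], ]; b <- M[tri[t, 2L], ]; cc <- M[tri[t, 3L], ]
    bc <- barycentric_coords(a, b, cc, px[todo], py[todo])
    inside <- bc[, 1L] >= -1e-12 & bc[, 2L] >= -1e-12 & bc[, 3L] >= -1e-12
    if (!any(inside)) next
    hit <- todo[inside]
    bch <- bc[inside, , drop = FALSE]
    rx <- bch[, 1L] * ref[tri[t, 1L], 1L] + bch[, 2L] * ref[tri[t, 2L], 1L] +
      bch[, 3L] * ref[tri[t, 3L], 1L]
    ry <- bch[, 1L] * ref[tri[t, 1L], 2L] + bch[, 2L] * ref[tri[t, 2L], 2L] +
      bch[, 3L] * ref[tri[t, 3L], 2L]
    img[cbind(py[hit] + 1L, px[hit] + 1L)] <-
      bilinear_sample(ras$img, rx - ras$x0, ry - ras$y0)
    assigned[hit] <- TRUE
  }
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(sz * sz, sd = noise_sd), sz, sz)
  list(image = img, landmarks = lmk)
}

#' Perturb an initialization away from the ground truth
#'
#' Two protocols: `bbox_jitter` places the mean shape by a similarity
#' transform fitted to a jittered ground-truth bounding box (translation and
#' scale noise proportional to `magnitude` times the face size);
#' `first_shape_param` reconstructs the ground truth through the model and
#' adds `magnitude * sqrt(eigenvalue)` to the first deformation parameter.
#' At `magnitude = 0` each mode returns its noise-free reconstruction.
#'
#' @param gt_landmarks ground-truth landmark vector.
#' @param world a `synthetic_world` (or any list with a `shape` model).
#' @param magnitude perturbation magnitude (dimensionless).
#' @param mode `"bbox_jitter"` or `"first_shape_param"`.
#' @param seed optional seed for the jitter draws.
#' @return perturbed landmark vector.
#' @export
perturb_init <- function(gt_landmarks, world, magnitude,
                         mode = c("bbox_jitter", "first_shape_param"),
                         seed = NULL) {
  mode <- match.arg(mode)
  model <- world$shape
  if (!is.null(seed)) set.seed(seed)
  if (mode == "first_shape_param") {
    p <- project_shape(model, gt_landmarks)
    idx <- model$n_sim + 1L
    p[idx] <- p[idx] + magnitude * sqrt(model$eigenvalues[idx])
    return(shape_instance(model, p))
  }
  G <- lmk_matrix(gt_landmarks)
  w <- diff(range(G[, 1L])); h <- diff(range(G[, 2L]))
  fs <- sqrt(w * h)
  ctr_g <- c(mean(range(G[, 1L])), mean(range(G[, 2L])))
  # detector-like bounded placement error: uniform in +/- magnitude * face
  # size per axis, and +/- magnitude relative scale
  jit_t <- magnitude * fs * stats::runif(2L, -1, 1)
  jit_s <- 1 + magnitude * stats::runif(1L, -1, 1)
  S0 <- lmk_matrix(model$s0)
  w0 <- diff(range(S0[, 1L])); h0 <- diff(range(S0[, 2L]))
  ctr_0 <- c(mean(range(S0[, 1L])), mean(range(S0[, 2L])))
  sc <- sqrt((w * h) / (w0 * h0)) * jit_s
  placed <- sweep(S0, 2L, ctr_0) * sc
  placed <- sweep(placed, 2L, ctr_g + jit_t, `+`)
  lmk_vector(placed)
}
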