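# Model training and the multi-resolution Gauss-Newton fitting driver.

default_phi_total <- function(n, m) n * max(1L, ceiling(m / 6))

apply_features <- function(model, img) {
  if (is.null(model$features) || model$features == "none") return(img)
  if (model$features == "dense_hog8") {
    return(dense_descriptor(img, N_f = model$feature_channels,
                            cell_size = model$feature_cell))
  }
  stop(sprintf("unknown feature kind '%s'", model$features), call. = FALSE)
}

scaled_shape_model <- function(model, sc) {
  if (sc == 1) return(model)
  shape_model_from_basis(model$s0 * sc, model$S, model$eigenvalues * sc^2,
                         n_sim = model$n_sim)
}

#' Train a shape-and-appearance model from annotated images
#'
#' Procrustes-aligns the training landmarks, builds the augmented shape
#' model in pixel units, then trains a multi-resolution appearance model:
#' one appearance PCA per pyramid level (images downscaled by
#' `scale^(levels - l)`), with the shape model shared across levels (scaled
#' per level). Steepest-descent images and the per-training-image Jacobians
#' used by the joint-alignment fitters are precomputed at training time.
#'
#' @param images list of image matrices.
#' @param landmarks list of landmark vectors.
#' @param n_shape number of PCA shape (deformation) components.
#' @param n_app number of appearance components per level.
#' @param type `"aam"` (holistic appearance, piecewise-affine warp) or
#'   `"gndpm"` (part-based appearance, translational motion model).
#' @param levels pyramid levels (default 2).
#' @param scale per-level downscaling factor (default 0.5).
#' @param N_s patch side for `type = "gndpm"` (odd, default 19).
#' @param features `"none"` or `"dense_hog8"` (dense gradient-orientation
#'   descriptors as the appearance signal).
#' @param feature_channels,feature_cell descriptor configuration.
#' @return object of class `gnaam_model`.
#' @export
train_aam <- function(images, landmarks, n_shape, n_app,
                      type = c("aam", "gndpm"),
                      levels = 2L, scale = 0.5, N_s = 19L,
                      features = "none", feature_channels = 8L,
                      feature_cell = 8L) {
  type <- match.arg(type)
  pro <- procrustes_align(landmarks)
  aligned_px <- lapply(pro$aligned, function(s) s * pro$mean_scale)
  shape <- build_shape_model(aligned_px, n_shape)

  model <- structure(list(
    type = type, n_levels = as.integer(levels), scale = scale,
    N_s = as.integer(N_s), features = features,
    feature_channels = as.integer(feature_channels),
    feature_cell = as.integer(feature_cell),
    shape = shape, levels = vector("list", levels)
  ), class = "gnaam_model")

  for (l in seq_len(levels)) {
    sc <- scale^(levels - l)
    shape_l <- scaled_shape_model(shape, sc)
    imgs_l <- lapply(images, function(im) apply_features(model, resize_image(im, sc)))
    lmks_l <- lapply(landmarks, function(s) s * sc)
    if (type == "aam") {
      frame <- build_reference_frame(shape_l$s0)
      app <- build_holistic_appearance(imgs_l, lmks_l, frame, n_app)
      jac <- warp_jacobian(shape_l, frame)
      train_vecs <- mapply(function(img, lmk) {
        flatten_samples(warp_image(img, lmk, frame))
      }, imgs_l, lmks_l, SIMPLIFY = FALSE)
    } else {
      frame <- NULL
      app <- build_part_appearance(imgs_l, lmks_l, shape_l, N_s = N_s, m = n_app)
      jac <- translational_shape_jacobian(shape_l)
      train_vecs <- mapply(function(img, lmk) {
        flatten_samples(sample_parts(img, lmk, shape_l$s0, N_s))
      }, imgs_l, lmks_l, SIMPLIFY = FALSE)
    }
    sds <- compute_steepest_descent(app, jac)
    G <- lapply(train_vecs, function(v) steepest_descent_of(app, v, jac))
    model$levels[[l]] <- list(scale = sc, shape = shape_l, frame = frame,
                              app = app, jac = jac, sds = sds, G = G,
                              states = list())
  }
  model
}

#' Fitting configuration
#'
#' @param iters iteration budget per pyramid level (recycled; default 25
#'   per level).
#' @param tol convergence tolerance on `max|dp|` (default 1e-6).
#' @param sparse_grid `"off"` or `"quarter"` (stride-2 sample grid).
#' @param phi_total total extended-subspace components for the E-POIC
#'   family; defaults to `n * ceiling(m / 6)` components split evenly across
#'   the n shape directions, mirroring the proportion of the reference
#'   configuration (1200 components for n = 19, m = 400).
#' @param record_trace keep the per-iteration trace (default TRUE).
#' @return a `fit_config` list.
#' @export
fit_config <- function(iters = c(25L, 25L), tol = 1e-6,
                       sparse_grid = c("off", "quarter"),
                       phi_total = NULL, record_trace = TRUE) {
  structure(list(iters = iters, tol = tol,
                 sparse_grid = match.arg(sparse_grid),
                 phi_total = phi_total, record_trace = record_trace),
            class = "fit_config")
}

# Precompute (and cache inside the model) the fitter state for one level.
algorithm_state <- function(lev, algorithm, weights = NULL, phi_total = NULL) {
  A <- lev$app$A
  sds <- lev$sds
  n <- ncol(sds$J0)
  m <- ncol(A)
  if (is.null(phi_total)) phi_total <- default_phi_total(n, m)
  if (algorithm %in% c("sic", "fast_sic", "afast_sic")) return(NULL)
  if (is.null(weights)) {
    return(switch(algorithm,
      poic = poic_precompute(sds, A),
      epoic_v1 = {
        ext <- build_extended_subspace(A, sds, phi_total)
        epoic_v1_precompute(sds, ext)
      },
      epoic_v2 = {
        st <- epoic_v2_precompute(lev$G, A)
        list(J_epoic = st$J_ja, H_epoic = st$H_ja)
      },
      epoic = {
        ext <- build_extended_subspace(A, sds, phi_total)
        epoic_precompute(lev$G, ext)
      }))
  }
  rows <- which(weights$keep)
  subset_projector <- function(B) {
    Bs <- B[rows, , drop = FALSE]
    if (ncol(Bs) == 0L) return(structure(list(apply = identity, A = Bs), class = "projector"))
    sv <- svd(Bs, nv = 0L)
    rank <- sum(sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10)
    Q <- sv$u[, seq_len(rank), drop = FALSE]
    structure(list(apply = function(X) X - Q %*% crossprod(Q, X), A = Q),
              class = "projector")
  }
  switch(algorithm,
    poic = {
      pr <- subset_projector(A)
      Jp <- pr$apply(sds$J0[rows, , drop = FALSE])
      list(J_poic = Jp, H_poic = crossprod(Jp), rows = rows)
    },
    epoic_v1 = {
      ext <- build_extended_subspace(A, sds, phi_total)
      pr <- subset_projector(ext$A_phi)
      Jp <- pr$apply(sds$J0[rows, , drop = FALSE])
      list(J_epoic = Jp, H_epoic = crossprod(Jp), rows = rows)
    },
    epoic_v2 = {
      pr <- subset_projector(A)
      Gs <- lapply(lev$G, function(g) g[rows, , drop = FALSE])
      st <- epoic_v2_precompute(Gs, pr)
      list(J_epoic = st$J_ja, H_epoic = st$H_ja, rows = rows)
    },
    epoic = {
      ext <- build_extended_subspace(A, sds, phi_total)
      pr <- subset_projector(ext$A_phi)
      Gs <- lapply(lev$G, function(g) g[rows, , drop = FALSE])
      st <- epoic_v2_precompute(Gs, pr)
      list(J_epoic = st$J_ja, H_epoic = st$H_ja, rows = rows)
    })
}

#' Precompute and cache fitter states inside a trained model
#'
#' Useful before fitting many images with the same algorithms: the
#' precomputations (projected Jacobians, Hessians, extended subspaces) are
#' stored per level and reused by [fit()].
#'
#' @param model a `gnaam_model`.
#' @param algorithms character vector of algorithm names.
#' @param phi_total extended-subspace size (see [fit_config()]).
#' @param sparse_grid `"off"` or `"quarter"`.
#' @return the model with populated state caches.
#' @export
precompute_fitters <- function(model, algorithms, phi_total = NULL,
                               sparse_grid = "off") {
  for (l in seq_len(model$n_levels)) {
    lev <- model$levels[[l]]
    weights <- fit_weights(model, lev, sparse_grid)
    for (alg in algorithms) {
      key <- paste(alg, sparse_grid, sep = "/")
      model$levels[[l]]$states[[key]] <-
        algorithm_state(lev, alg, weights = weights, phi_total = phi_total)
    }
  }
  model
}

fit_weights <- function(model, lev, sparse_grid) {
  if (sparse_grid == "off") return(NULL)
  if (model$type == "aam") {
    make_sparse_grid(lev$frame, C = lev$app$C, stride = 2L)
  } else {
    N_s <- model$N_s
    offs <- patch_offsets(N_s)
    kp_patch <- (offs[, 1L] %% 2L == 0L) & (offs[, 2L] %% 2L == 0L)
    kp <- rep(kp_patch, times = model$shape$u)
    sample_weights_from_logical(rep(kp, each = lev$app$C), C = lev$app$C)
  }
}

lmk_in_image <- function(lmk, dims) {
  M <- lmk_matrix(lmk)
  any(M[, 1L] >= 0 & M[, 1L] <= dims[2L] - 1 &
      M[, 2L] >= 0 & M[, 2L] <= dims[1L] - 1)
}

#' Fit a trained model to an image
#'
#' Multi-resolution Gauss-Newton fitting: per level, the image is resampled
#' and the current landmark estimate projected onto the level's shape model;
#' each iteration samples the image under the current warp, forms the
#' residual, computes the chosen algorithm's update, composes it inversely
#' with the current warp (which reduces to subtraction for the translational
#' motion model of part-based models), and updates the appearance
#' coefficients where the algorithm produces them. Simultaneous algorithms
#' (`sic`, `fast_sic`, `afast_sic`) track `c` across iterations starting
#' from the projection of the first residual; project-out algorithms report
#' `c` from the final residual only. Iteration stops at the budget or when
#' `max|dp| < tol`.
#'
#' @param image image matrix (grayscale; descriptor channels are computed
#'   internally when the model was trained with features).
#' @param init_landmarks initial landmark vector (e.g. from
#'   [init_from_bbox()] or [perturb_init()]).
#' @param model a `gnaam_model`.
#' @param algorithm one of `"sic"`, `"fast_sic"`, `"afast_sic"`, `"poic"`,
#'   `"epoic_v1"`, `"epoic_v2"`, `"epoic"`.
#' @param config a [fit_config()].
#' @return object of class `fit_result`: list with `landmarks`, `p`, `c`,
#'   `trace` (data.frame: level, iteration, residual_norm, dp_norm),
#'   `trace_landmarks` and `trace_p` (per-iteration landmark vectors and
#'   parameter vectors, in each level's own scale for `trace_p`),
#'   `converged`, `diverged`, `iterations`, `warnings`.
#' @export
fit <- function(image, init_landmarks, model,
                algorithm = c("fast_sic", "afast_sic", "sic", "poic",
                              "epoic_v1", "epoic_v2", "epoic"),
                config = fit_config()) {
  algorithm <- match.arg(algorithm)
  check_landmarks(init_landmarks, u = model$shape$u)
  lmk <- init_landmarks
  trace <- list(); trace_lmk <- list(); trace_p <- list()
  warns <- character(); diverged <- FALSE
  total_iters <- 0L
  p_final <- NULL; c_final <- NULL

  for (l in seq_len(model$n_levels)) {
    lev <- model$levels[[l]]
    sc <- lev$scale
    img_l <- apply_features(model, resize_image(image, sc))
    iters <- config$iters[min(l, length(config$iters))]
    res <- withCallingHandlers(
      fit_level(img_l, lmk * sc, lev, model, algorithm, iters, config),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    total_iters <- total_iters + res$iters_run
    if (res$iters_run > 0L || res$diverged) lmk <- res$lmk / sc
    p_final <- res$p; c_final <- res$c
    if (config$record_trace && nrow(res$trace) > 0L) {
      res$trace$level <- l
      trace[[l]] <- res$trace
      trace_lmk[[l]] <- lapply(res$trace_lmk, function(s) s / sc)
      trace_p[[l]] <- res$trace_p
    }
    if (res$diverged) { diverged <- TRUE; break }
  }
  structure(list(
    landmarks = lmk, p = p_final, c = c_final,
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(level = integer(), iteration = integer(),
                 residual_norm = numeric(), dp_norm = numeric()),
    trace_landmarks = if (length(trace_lmk)) do.call(c, trace_lmk) else list(),
    trace_p = if (length(trace_p)) do.call(c, trace_p) else list(),
    converged = !diverged && total_iters > 0L,
    diverged = diverged, iterations = total_iters,
    warnings = unique(warns)
  ), class = "fit_result")
}

fit_level <- function(img, lmk, lev, model, algorithm, iters, config) {
  shape <- lev$shape
  app <- lev$app
  A <- app$A; m <- ncol(A)
  sds <- lev$sds
  parts <- model$type == "gndpm"
  mode <- if (parts) "translational" else "piecewise_affine"
  weights <- fit_weights(model, lev, config$sparse_grid)
  key <- paste(algorithm, config$sparse_grid, sep = "/")
  state <- lev$states[[key]]
  if (is.null(state) && !(algorithm %in% c("sic", "fast_sic", "afast_sic"))) {
    state <- algorithm_state(lev, algorithm, weights = weights,
                             phi_total = config$phi_total)
  }
  simultaneous <- algorithm %in% c("sic", "fast_sic", "afast_sic")
  dims <- dim(img)[1:2]

  if (parts) {
    # freeze the similarity normalization at the level's initialization and
    # fit translationally in the reference coordinate system
    sim <- similarity_to_reference(lmk, shape$s0)
    to_ref <- function(L) sweep(sim$s * L %*% t(sim$R), 2L, sim$t, `+`)
    to_img <- function(L) sweep(L, 2L, sim$t) %*% sim$R / sim$s
    offs <- patch_offsets(model$N_s)
    sample_at <- function(lmk_ref) {
      L <- lmk_matrix(lmk_ref)
      xs_ref <- rep(L[, 1L], each = nrow(offs)) + rep(offs[, 1L], times = nrow(L))
      ys_ref <- rep(L[, 2L], each = nrow(offs)) + rep(offs[, 2L], times = nrow(L))
      P <- cbind(xs_ref, ys_ref)
      Pi <- to_img(P)
      flatten_samples(sample_channels(img, Pi[, 1L], Pi[, 2L]))
    }
    lmk_work <- lmk_vector(to_ref(lmk_matrix(lmk)))
  } else {
    sample_at <- function(lmk_cur) {
      flatten_samples(warp_image(img, lmk_cur, lev$frame))
    }
    lmk_work <- lmk
  }

  p <- project_shape(shape, lmk_work)
  cvec <- NULL
  trace <- data.frame(iteration = integer(), residual_norm = numeric(),
                      dp_norm = numeric())
  trace_lmk <- list()
  trace_p <- list()
  iters_run <- 0L
  div <- FALSE
  last_r0 <- NULL

  for (it in seq_len(iters)) {
    cur <- shape_instance(shape, p)
    cur_img <- if (parts) lmk_vector(to_img(lmk_matrix(cur))) else cur
    if (!lmk_in_image(cur_img, dims)) { div <- TRUE; break }
    Ivec <- sample_at(cur)
    r0 <- Ivec - app$A0
    last_r0 <- r0
    if (simultaneous && is.null(cvec)) {
      cvec <- if (m > 0L) drop(crossprod(A, r0)) else numeric(0)
    }
    if (config$sparse_grid == "off") {
      upd <- switch(algorithm,
        sic = {
          J <- combine_jacobian(sds, cvec)
          sic_update(r0 - if (m > 0L) A %*% cvec else 0, J, A)
        },
        fast_sic = fast_sic_update(r0, combine_jacobian(sds, cvec), A, cvec),
        afast_sic = afast_sic_update(r0, combine_jacobian(sds, cvec), A, cvec),
        poic = poic_update(r0, state),
        epoic_v1 = epoic_v1_update(r0, state),
        epoic_v2 = ,
        epoic = epoic_update(r0, state)
      )
    } else {
      if (simultaneous) {
        J <- combine_jacobian(sds, cvec)
        resid <- if (algorithm == "sic") r0 - if (m > 0L) A %*% cvec else 0 else r0
        upd <- weighted_update(resid, J, A, cvec, weights, algorithm)
      } else {
        upd <- switch(algorithm,
          poic = poic_update(r0[state$rows], state),
          epoic_v1 = ,
          epoic_v2 = ,
          epoic = epoic_update(r0[state$rows], state))
      }
    }
    dp <- upd$dp
    if (simultaneous && m > 0L) cvec <- cvec + upd$dc
    rnorm_val <- if (simultaneous && m > 0L) {
      sqrt(sum((r0 - A %*% cvec)^2))
    } else sqrt(sum(r0^2))
    p <- inverse_compositional_update(p, dp, shape, mode, frame = lev$frame)
    iters_run <- it
    if (config$record_trace) {
      trace <- rbind(trace, data.frame(iteration = it, residual_norm = rnorm_val,
                                       dp_norm = max(abs(dp))))
      cur2 <- shape_instance(shape, p)
      trace_lmk[[length(trace_lmk) + 1L]] <-
        if (parts) lmk_vector(to_img(lmk_matrix(cur2))) else cur2
      trace_p[[length(trace_p) + 1L]] <- p
    }
    if (max(abs(dp)) < config$tol) break
  }

  final_ref <- if (iters_run > 0L) shape_instance(shape, p) else lmk_work
  final <- if (parts) lmk_vector(to_img(lmk_matrix(final_ref))) else final_ref
  if (!simultaneous && m > 0L) {
    r_end <- tryCatch(sample_at(final_ref) - app$A0, error = function(e) last_r0)
    cvec <- if (is.null(r_end)) NULL else drop(crossprod(A, r_end))
  }
  list(lmk = final, p = p, c = cvec, trace = trace, trace_lmk = trace_lmk,
       trace_p = trace_p, iters_run = iters_run, diverged = div)
}

#' Place the mean shape inside a bounding box
#'
#' Scales the model mean shape so the geometric means of the bounding-box
#' sides match, and centers it in the box — the standard detector-driven
#' initialization.
#'
#' @param model a `gnaam_model` or `shape_model`.
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`.
#' @return landmark vector.
#' @export
init_from_bbox <- function(model, bbox) {
  shape <- if (inherits(model, "gnaam_model")) model$shape else model
  S0 <- lmk_matrix(shape$s0)
  w0 <- diff(range(S0[, 1L])); h0 <- diff(range(S0[, 2L]))
  ctr0 <- c(mean(range(S0[, 1L])), mean(range(S0[, 2L])))
  w <- bbox[3L] - bbox[1L]; h <- bbox[4L] - bbox[2L]
  sc <- sqrt((w * h) / (w0 * h0))
  ctr <- c((bbox[1L] + bbox[3L]) / 2, (bbox[2L] + bbox[4L]) / 2)
  lmk_vector(sweep(sweep(S0, 2L, ctr0) * sc, 2L, ctr, `+`))
}
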