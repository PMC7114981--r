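test_that("a zero iteration budget returns the initialization unchanged", {
  w <- small_world()
  model <- small_model()
  set.seed(91)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c)
  init <- perturb_init(inst$landmarks, w, 0.05, "bbox_jitter", seed = 2)
  fr <- fit(inst$image, init, model, "fast_sic", fit_config(iters = 0))
  expect_identical(fr$landmarks, init)
  expect_equal(fr$iterations, 0L)
  expect_false(fr$converged)
})

test_that("ground-truth initialization does not drift on noise-free renders", {
  w <- small_world()
  model <- small_model()
  set.seed(92)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c, noise_sd = 0)
  fs <- face_size(inst$landmarks)
  init_err <- normalized_pt_pt_error(
    oracle_baseline(model$shape, inst$landmarks), inst$landmarks, fs)
  for (alg in c("fast_sic", "sic")) {
    fr <- fit(inst$image, inst$landmarks, model, alg,
              fit_config(iters = 15, record_trace = FALSE))
    err <- normalized_pt_pt_error(fr$landmarks, inst$landmarks, fs)
    expect_lt(err, 0.01)
  }
})

test_that("the trace satisfies the landmark and budget contracts", {
  w <- small_world()
  model <- small_model()
  set.seed(93)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c)
  init <- perturb_init(inst$landmarks, w, 0.05, "bbox_jitter", seed = 4)
  cfg <- fit_config(iters = 8)
  fr <- fit(inst$image, init, model, "fast_sic", cfg)
  expect_lte(nrow(fr$trace), 8)
  expect_equal(length(fr$trace_landmarks), nrow(fr$trace))
  # every trace entry's landmarks are the shape instance of its parameters
  lev <- model$levels[[model$n_levels]]
  for (k in seq_along(fr$trace_p)) {
    expect_equal(fr$trace_landmarks[[k]],
                 shape_instance(lev$shape, fr$trace_p[[k]]) / lev$scale,
                 tolerance = 1e-12)
  }
  expect_true(all(fr$trace$residual_norm >= 0))
})

test_that("Fast-SIC and aFast-SIC produce closely matching fits", {
  w <- small_world()
  model <- small_model()
  finals <- sapply(1:5, function(t) {
    set.seed(200 + t)
    pc <- draw_parameters(w)
    inst <- render_instance(w, pc$p, pc$c, noise_sd = 0.005)
    init <- perturb_init(inst$landmarks, w, 0.05, "bbox_jitter", seed = 300 + t)
    cfg <- fit_config(iters = 25, record_trace = FALSE)
    f1 <- fit(inst$image, init, model, "fast_sic", cfg)
    f2 <- fit(inst$image, init, model, "afast_sic", cfg)
    max(abs(f1$landmarks - f2$landmarks))
  })
  expect_lt(median(finals), 0.5)  # pixels
})

test_that("simultaneous fitting drives the residual down monotonically in the median", {
  w <- small_world()
  model <- small_model()
  traces <- lapply(1:5, function(t) {
    set.seed(400 + t)
    pc <- draw_parameters(w)
    inst <- render_instance(w, pc$p, pc$c, noise_sd = 0)
    init <- perturb_init(inst$landmarks, w, 0.03, "bbox_jitter", seed = 500 + t)
    fr <- fit(inst$image, init, model, "fast_sic", fit_config(iters = 12))
    fr$trace$residual_norm
  })
  len <- min(lengths(traces))
  med <- apply(sapply(traces, function(x) x[seq_len(len)]), 1, median)
  # non-increasing up to the interpolation noise floor, with a clear
  # overall decrease
  expect_true(all(diff(med) <= 0.01 * med[1]))
  expect_lt(med[len], 0.5 * med[1])
})

test_that("an initialization far outside the image is flagged as diverged", {
  w <- small_world()
  model <- small_model()
  set.seed(94)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c)
  init <- inst$landmarks + 500
  fr <- fit(inst$image, init, model, "fast_sic", fit_config(iters = 5))
  expect_true(fr$diverged)
  expect_false(fr$converged)
})

test_that("sparse-grid fitting tracks the full-grid fit", {
  w <- small_world()
  model <- precompute_fitters(small_model(), "poic", sparse_grid = "quarter")
  set.seed(95)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c, noise_sd = 0.005)
  init <- perturb_init(inst$landmarks, w, 0.03, "bbox_jitter", seed = 6)
  cfg_full <- fit_config(iters = 20, record_trace = FALSE)
  cfg_grid <- fit_config(iters = 20, sparse_grid = "quarter", record_trace = FALSE)
  for (alg in c("fast_sic", "poic")) {
    f_full <- fit(inst$image, init, model, alg, cfg_full)
    f_grid <- fit(inst$image, init, model, alg, cfg_grid)
    e_full <- normalized_pt_pt_error(f_full$landmarks, inst$landmarks)
    e_grid <- normalized_pt_pt_error(f_grid$landmarks, inst$landmarks)
    expect_lt(abs(e_grid - e_full), 0.02)
  }
})

test_that("part-based models fit with the translational motion model", {
  w <- small_world()
  set.seed(96)
  train <- lapply(1:12, function(i) {
    pc <- draw_parameters(w)
    render_instance(w, pc$p, pc$c, noise_sd = 0.005)
  })
  gndpm <- train_aam(lapply(train, `[[`, "image"), lapply(train, `[[`, "landmarks"),
                     n_shape = 3, n_app = 4, type = "gndpm", levels = 1, N_s = 9L)
  expect_equal(gndpm$levels[[1]]$app$N, w$shape$u * 81)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c, noise_sd = 0.005)
  init <- perturb_init(inst$landmarks, w, 0.03, "bbox_jitter", seed = 7)
  fr <- fit(inst$image, init, gndpm, "fast_sic", fit_config(iters = 25, record_trace = FALSE))
  err <- normalized_pt_pt_error(fr$landmarks, inst$landmarks)
  init_err <- normalized_pt_pt_error(init, inst$landmarks)
  expect_lt(err, init_err / 2)
})

test_that("descriptor-based models can be trained and fitted", {
  w <- small_world()
  set.seed(97)
  train <- lapply(1:8, function(i) {
    pc <- draw_parameters(w)
    render_instance(w, pc$p, pc$c, noise_sd = 0.005)
  })
  fm <- train_aam(lapply(train, `[[`, "image"), lapply(train, `[[`, "landmarks"),
                  n_shape = 3, n_app = 4, type = "aam", levels = 1,
                  features = "dense_hog8", feature_channels = 8L, feature_cell = 6L)
  expect_equal(fm$levels[[1]]$app$C, 8L)
  expect_equal(length(fm$levels[[1]]$app$A0), 8L * fm$levels[[1]]$frame$N)
  pc <- draw_parameters(w)
  inst <- render_instance(w, pc$p, pc$c, noise_sd = 0.005)
  init <- perturb_init(inst$landmarks, w, 0.08, "bbox_jitter", seed = 8)
  fr <- fit(inst$image, init, fm, "fast_sic", fit_config(iters = 30, record_trace = FALSE))
  err <- normalized_pt_pt_error(fr$landmarks, inst$landmarks)
  init_err <- normalized_pt_pt_error(init, inst$landmarks)
  # descriptor models on smooth band-limited textures carry a coarser
  # localization floor than intensities (contrast normalization removes
  # most amplitude information); the fit must still contract a sizeable
  # perturbation to that floor
  expect_lt(err, init_err)
  expect_lt(err, 0.06)
})

test_that("bounding-box initialization places the mean shape inside the box", {
  model <- small_model()
  bbox <- c(10, 15, 60, 70)
  init <- init_from_bbox(model, bbox)
  M <- lmk_matrix(init)
  expect_true(all(M[, 1] >= 5 & M[, 1] <= 65))
  expect_true(all(M[, 2] >= 10 & M[, 2] <= 75))
  ctr <- c(mean(range(M[, 1])), mean(range(M[, 2])))
  expect_equal(ctr, c(35, 42.5), tolerance = 1e-9)
})
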