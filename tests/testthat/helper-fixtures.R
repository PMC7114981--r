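# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

rand_orthonormal <- function(N, m) {
  if (m == 0L) return(matrix(0, N, 0L))
  qr.Q(qr(matrix(rnorm(N * m), N, m)))
}

# ring-shaped random landmark sets around a common base shape
random_shapes <- function(D, u, sd = 0.05, seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = u + 1L)[-(u + 1L)]
  base <- lmk_vector(cbind(cos(th), sin(th)))
  lapply(seq_len(D), function(i) base + rnorm(2 * u, sd = sd))
}

# a small synthetic world, shared
small_world <- function() memo("small_world", function() {
  make_world(u = 12L, n = 3L, m = 4L, image_size = 72L, seed = 9L)
})

# a trained holistic model on renders of the small world
small_model <- function() memo("small_model", function() {
  w <- small_world()
  set.seed(501)
  train <- lapply(1:15, function(i) {
    pc <- draw_parameters(w)
    render_instance(w, pc$p, pc$c, noise_sd = 0.005)
  })
  train_aam(lapply(train, `[[`, "image"), lapply(train, `[[`, "landmarks"),
            n_shape = 3, n_app = 4, type = "aam", levels = 1)
})

# a single-triangle frame with a 2-column pure-translation shape model
translation_fixture <- function() memo("translation_fixture", function() {
  s0 <- lmk_vector(rbind(c(0, 0), c(20, 0), c(0, 20)))
  S <- cbind(rep(c(1, 0), 3) / sqrt(3), rep(c(0, 1), 3) / sqrt(3))
  model <- gnaam:::shape_model_from_basis(s0, S, c(1, 1), n_sim = 0L)
  frame <- build_reference_frame(s0)
  list(model = model, frame = frame)
})

# the full 100-trial recovery suite (used by the acceptance checks), run once
suite_result <- function() memo("suite_result", function() {
  run_recovery_suite(seed = 1L, n_trials = 100L)
})

# sine-based principal angles (accurate for angles below sqrt(eps), where
# acos of the cosine saturates)
principal_angles <- function(Q1, Q2) {
  R <- Q2 - Q1 %*% crossprod(Q1, Q2)
  asin(pmin(svd(R)$d, 1))
}
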