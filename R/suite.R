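# End-to-end synthetic recovery suite: trains a model from rendered
# instances of a known world and measures landmark-recovery accuracy of the
# fitting algorithms under perturbed initializations.

#' Run the synthetic landmark-recovery suite
#'
#' Builds a synthetic world, renders a training set, trains a model with the
#' full pipeline, then fits `n_trials` freshly rendered test instances whose
#' initialization is perturbed by bounding-box jitter, recording the
#' normalized point-to-point error of every algorithm on every trial.
#' Deterministic given `seed`.
#'
#' @param seed master seed.
#' @param n_trials number of test renders (default 100).
#' @param algorithms algorithms to evaluate.
#' @param u,n,m,image_size world dimensions (see [make_world()]).
#' @param n_train training-set size (default 40).
#' @param magnitude bounding-box jitter magnitude (default 0.05).
#' @param noise_sd additive image noise (default 0.005 intensity units).
#' @param levels,iters pyramid levels and per-level iteration budget for the
#'   suite (defaults: single level, 60 iterations — a budget generous enough
#'   for the slower-converging project-out family).
#' @param phi_total extended-subspace size (see [fit_config()]).
#' @param sparse_grid `"off"` or `"quarter"`.
#' @return list with `errors` (n_trials x algorithms matrix of normalized
#'   errors), `init_errors`, `oracle_errors`, `success` (fraction of trials
#'   below 0.015 per algorithm), `model`, `world`.
#' @export
run_recovery_suite <- function(seed = 1L, n_trials = 100L,
                               algorithms = c("fast_sic", "afast_sic",
                                              "epoic", "poic"),
                               u = 20L, n = 6L, m = 12L, image_size = 96L,
                               n_train = 40L, magnitude = 0.05,
                               noise_sd = 0.005,
                               levels = 1L, iters = 60L,
                               phi_total = NULL, sparse_grid = "off") {
  world <- make_world(u = u, n = n, m = m, image_size = image_size, seed = seed)
  set.seed(seed + 1000L)
  train <- lapply(seq_len(n_train), function(i) {
    pc <- draw_parameters(world)
    render_instance(world, pc$p, pc$c, noise_sd = noise_sd)
  })
  model <- train_aam(lapply(train, `[[`, "image"),
                     lapply(train, `[[`, "landmarks"),
                     n_shape = n, n_app = m, type = "aam", levels = levels)
  model <- precompute_fitters(model, setdiff(algorithms, c("sic", "fast_sic", "afast_sic")),
                              phi_total = phi_total, sparse_grid = sparse_grid)
  cfg <- fit_config(iters = rep(iters, levels), sparse_grid = sparse_grid,
                    phi_total = phi_total, record_trace = FALSE)

  errors <- matrix(NA_real_, n_trials, length(algorithms),
                   dimnames = list(NULL, algorithms))
  init_errors <- oracle_errors <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(seed + 10000L + t)
    pc <- draw_parameters(world)
    inst <- render_instance(world, pc$p, pc$c, noise_sd = noise_sd)
    fs <- face_size(inst$landmarks)
    init <- perturb_init(inst$landmarks, world, magnitude, "bbox_jitter")
    init_errors[t] <- normalized_pt_pt_error(init, inst$landmarks, fs)
    oracle_errors[t] <- normalized_pt_pt_error(
      oracle_baseline(model$shape, inst$landmarks), inst$landmarks, fs)
    for (alg in algorithms) {
      fr <- fit(inst$image, init, model, algorithm = alg, config = cfg)
      errors[t, alg] <- normalized_pt_pt_error(fr$landmarks, inst$landmarks, fs)
    }
  }
  list(errors = errors, init_errors = init_errors,
       oracle_errors = oracle_errors,
       success = colMeans(errors < 0.015),
       model = model, world = world)
}
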