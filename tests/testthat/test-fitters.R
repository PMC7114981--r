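random_fixture <- function(N, n, m, seed) {
  set.seed(seed)
  list(A = rand_orthonormal(N, m),
       J = matrix(rnorm(N * n), N, n),
       r0 = rnorm(N),
       c = rnorm(m))
}

test_that("Fast-SIC reproduces the simultaneous update exactly", {
  for (seed in 1:10) {
    fx <- random_fixture(sample(30:150, 1), sample(2:5, 1), sample(1:8, 1), seed)
    su <- sic_update(fx$r0 - fx$A %*% fx$c, fx$J, fx$A)
    fu <- fast_sic_update(fx$r0, fx$J, fx$A, fx$c)
    expect_lt(max(abs(su$dp - fu$dp)) / max(abs(su$dp)), 1e-8)
    expect_lt(max(abs(su$dc - fu$dc)) / max(abs(su$dc), 1e-8), 1e-8)
    # stacked pseudo-inverse and Schur-complement oracles
    o <- oracle_sic_solve(fx$r0 - fx$A %*% fx$c, fx$A, fx$J)
    expect_lt(max(abs(o$dp - su$dp)), 1e-8)
    expect_lt(max(abs(oracle_schur_dp(fx$r0 - fx$A %*% fx$c, fx$A, fx$J) - su$dp)), 1e-8)
  }
})

test_that("updates vanish on zero or fully explained residuals", {
  fx <- random_fixture(80, 3, 4, 99)
  z <- sic_update(rep(0, 80), fx$J, fx$A)
  expect_equal(z$dp, rep(0, 3))
  expect_equal(z$dc, rep(0, 4))
  # residual orthogonal to span([A J]): Fast-SIC dp = 0
  r <- rnorm(80)
  B <- cbind(fx$A, fx$J)
  r <- drop(r - B %*% solve(crossprod(B), crossprod(B, r)))
  fu <- fast_sic_update(r, fx$J, fx$A, rep(0, 4))
  expect_lt(max(abs(fu$dp)), 1e-9)
  # POIC: residual inside span(A) gives dp = 0
  st <- poic_precompute(list(J0 = fx$J), fx$A)
  pu <- poic_update(drop(fx$A %*% rnorm(4)), st)
  expect_lt(max(abs(pu$dp)), 1e-9)
})

test_that("aFast-SIC is one sweep of block coordinate descent and degenerates correctly", {
  fx <- random_fixture(100, 3, 5, 7)
  af <- afast_sic_update(fx$r0, fx$J, fx$A, fx$c)
  # alternation oracle: minimize over dc (dp = 0), then dp, then dc again
  dc1 <- drop(crossprod(fx$A, fx$r0)) - fx$c
  r1 <- fx$r0 - fx$A %*% (fx$c + dc1)
  dp <- drop(solve(crossprod(fx$J), crossprod(fx$J, r1)))
  dc2 <- drop(crossprod(fx$A, fx$r0 - fx$J %*% dp)) - fx$c
  expect_equal(af$dp, dp, tolerance = 1e-10)
  expect_equal(af$dc, dc2, tolerance = 1e-10)

  # m = 0: identical to Fast-SIC
  A0 <- matrix(0, 100, 0)
  expect_equal(afast_sic_update(fx$r0, fx$J, A0)$dp,
               fast_sic_update(fx$r0, fx$J, A0)$dp)

  # c = 0 and J orthogonal to A: identical to Fast-SIC
  Jperp <- fx$J - fx$A %*% crossprod(fx$A, fx$J)
  expect_equal(afast_sic_update(fx$r0, Jperp, fx$A, rep(0, 5))$dp,
               fast_sic_update(fx$r0, Jperp, fx$A, rep(0, 5))$dp,
               tolerance = 1e-10)
})

test_that("POIC equals Fast-SIC at c = 0 with no appearance Jacobians, and matches the dense oracle", {
  fx <- random_fixture(150, 4, 6, 13)
  st <- poic_precompute(list(J0 = fx$J), fx$A)
  pu <- poic_update(fx$r0, st)
  fu <- fast_sic_update(fx$r0, fx$J, fx$A, rep(0, 6))
  expect_equal(pu$dp, fu$dp, tolerance = 1e-10)
  Pd <- oracle_projector(fx$A)
  Jp <- Pd %*% fx$J
  dp_d <- drop(solve(crossprod(Jp), crossprod(Jp, fx$r0)))
  expect_lt(max(abs(pu$dp - dp_d)), 1e-9)
})

test_that("the extended subspace annihilates what it should", {
  w <- small_world()
  wj <- warp_jacobian(w$shape, w$frame)
  sds <- compute_steepest_descent(w$app, wj)
  A <- w$app$A
  ext <- build_extended_subspace(A, sds, l_total = w$shape$n * w$app$m)
  for (i in seq_len(w$app$m)) {
    expect_lt(max(abs(ext$projector$apply(sds$Ji[[i]]))), 1e-8)
  }
  expect_lt(max(abs(ext$projector$apply(A))), 1e-10)
  # dense pseudo-inverse oracle (on a size-guarded random fixture)
  set.seed(41)
  B <- cbind(rand_orthonormal(250, 3), matrix(rnorm(250 * 4), 250, 4))
  Pd <- oracle_extended_projector(B)
  X <- matrix(rnorm(250 * 3), 250, 3)
  sv <- svd(B, nv = 0)
  Q <- sv$u[, sv$d > sv$d[1] * 1e-10, drop = FALSE]
  expect_lt(max(abs((X - Q %*% crossprod(Q, X)) - Pd %*% X)), 1e-9)
  expect_lt(max(abs(Pd %*% Pd - Pd)), 1e-9)
})

test_that("joint-alignment precomputation satisfies the cross-term identity", {
  set.seed(42)
  G <- lapply(1:3, function(i) matrix(rnorm(180 * 3), 180, 3))
  A <- rand_orthonormal(180, 5)
  st <- epoic_v2_precompute(G, A)
  Pd <- oracle_projector(A)
  Gsum <- Reduce(`+`, G)
  H_poic <- t(Gsum) %*% Pd %*% Gsum
  cross <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j) cross <- cross + t(G[[i]]) %*% Pd %*% G[[j]]
  expect_lt(max(abs(H_poic - st$H_ja - cross)), 1e-9)
  # H_ja is symmetric PSD
  expect_lt(max(abs(st$H_ja - t(st$H_ja))), 1e-9)
  expect_gt(min(eigen(st$H_ja, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8 * sum(diag(st$H_ja)))
  # D = 1: no cross terms possible, H_ja equals the projected-out Hessian
  st1 <- epoic_v2_precompute(G[1], A)
  expect_equal(st1$H_ja, t(G[[1]]) %*% Pd %*% G[[1]], tolerance = 1e-10)
})

test_that("the combined E-POIC update degenerates to its parents", {
  set.seed(43)
  N <- 160; n <- 3; m <- 4
  A <- rand_orthonormal(N, m)
  G <- lapply(1:3, function(i) matrix(rnorm(N * n), N, n))
  r0 <- rnorm(N)
  # empty Phi: combined update equals E-POIC-v2
  sds_dummy <- structure(list(J0 = Reduce(`+`, G), Ji = list(), n = n), class = "sds_set")
  ext_empty <- build_extended_subspace(A, sds_dummy, l_total = n)
  st_comb <- epoic_precompute(G, ext_empty)
  st_v2 <- epoic_v2_precompute(G, A)
  expect_equal(epoic_update(r0, st_comb)$dp,
               epoic_v2_update(r0, st_v2)$dp, tolerance = 1e-9)
  # empty Phi and D = 1: equals POIC with J0 = G1
  st1 <- epoic_precompute(G[1], ext_empty)
  stp <- poic_precompute(list(J0 = G[[1]]), A)
  expect_equal(epoic_update(r0, st1)$dp, poic_update(r0, stp)$dp, tolerance = 1e-9)
  # dense-projector oracle for E-POIC-v1
  sds2 <- structure(list(J0 = G[[1]], Ji = lapply(1:m, function(i) matrix(rnorm(N * n), N, n)),
                         n = n), class = "sds_set")
  ext <- build_extended_subspace(A, sds2, l_total = n * 2)
  stv1 <- epoic_v1_precompute(sds2, ext)
  Pd <- oracle_extended_projector(ext$A_phi)
  Jp <- Pd %*% G[[1]]
  expect_equal(epoic_v1_update(r0, stv1)$dp,
               drop(solve(crossprod(Jp), crossprod(Jp, r0))), tolerance = 1e-8)
})

test_that("weighted updates match the explicit diagonal-matrix oracle and reduce exactly at W = E", {
  fx <- random_fixture(200, 3, 5, 17)
  keep <- rep(FALSE, 200); keep[seq(1, 200, by = 2)] <- TRUE
  wts <- sample_weights_from_logical(keep)
  # quarter-style grid vs dense diagonal oracle
  wu <- weighted_update(fx$r0 - fx$A %*% fx$c, fx$J, fx$A, fx$c, wts, "sic")
  ow <- oracle_weighted_solve(fx$r0 - fx$A %*% fx$c, fx$A, fx$J, keep)
  expect_lt(max(abs(wu$dp - ow$dp)), 1e-10)
  expect_lt(max(abs(wu$dc - ow$dc)), 1e-10)

  # all-ones weights: bitwise identical to the unweighted updates
  wfull <- sample_weights_from_logical(rep(TRUE, 200))
  expect_identical(weighted_update(fx$r0, fx$J, fx$A, fx$c, wfull, "fast_sic"),
                   fast_sic_update(fx$r0, fx$J, fx$A, fx$c))
  expect_identical(weighted_update(fx$r0, fx$J, fx$A, fx$c, wfull, "afast_sic"),
                   afast_sic_update(fx$r0, fx$J, fx$A, fx$c))

  # keep-one-row with n = 1, m = 0: scalar least squares
  J1 <- matrix(rnorm(50), 50, 1)
  r1 <- rnorm(50)
  k1 <- rep(FALSE, 50); k1[17] <- TRUE
  w1 <- sample_weights_from_logical(k1)
  u1 <- weighted_update(r1, J1, matrix(0, 50, 0), numeric(0), w1, "fast_sic")
  expect_equal(u1$dp, r1[17] / J1[17, 1], tolerance = 1e-12)

  # under-determined grids are refused with a diagnostic
  k2 <- rep(FALSE, 200); k2[1:3] <- TRUE
  expect_error(weighted_update(fx$r0, fx$J, fx$A, fx$c,
                               sample_weights_from_logical(k2), "sic"),
               "under-determined")
})

test_that("near-singular Hessians trigger the logged ridge fallback", {
  N <- 60
  J <- cbind(rnorm(N), 0)  # rank-deficient Jacobian
  expect_warning(u <- fast_sic_update(rnorm(N), J, matrix(0, N, 0)), "ridge")
  expect_true(all(is.finite(u$dp)))
})

test_that("flop counts scale with the advertised complexity families", {
  N <- 1e5; n <- 10; m <- 200
  algs <- c("sic", "fast_sic", "afast_sic", "poic", "epoic_v1", "epoic_v2", "epoic")
  # every update's per-pixel work is linear in N (solve terms are negligible
  # at this size)
  for (alg in algs) {
    expect_equal(update_flops(alg, 2 * N, n, m) / update_flops(alg, N, n, m),
                 2, tolerance = 0.01)
  }
  # m-dependence classes, as exact finite differences of the count
  # polynomial: SIC is quadratic in m, Fast-SIC and aFast-SIC are linear,
  # the project-out family is constant
  d1 <- function(alg, mm) update_flops(alg, N, n, mm + 50) - update_flops(alg, N, n, mm)
  d2 <- function(alg, mm) d1(alg, mm + 50) - d1(alg, mm)
  expect_gt(d2("sic", m), 0)
  # quadratic in m at leading order: constant d2 (up to the small cubic
  # solve term, irrelevant at m << N)
  expect_equal(d2("sic", m), d2("sic", 2 * m), tolerance = 0.01)
  expect_identical(d2("fast_sic", m), 0)                    # linear: zero d2
  expect_identical(d2("afast_sic", m), 0)
  expect_identical(d1("poic", m), 0)                        # constant in m
  # the m-slope of Fast-SIC grows with n (the nmN term) while aFast-SIC's is
  # n-free (the (n+m)N term)
  slope <- function(alg, nn) update_flops(alg, N, nn, m + 1) - update_flops(alg, N, nn, m)
  expect_equal(slope("fast_sic", 2 * n) / slope("fast_sic", n), 2, tolerance = 0.05)
  expect_identical(slope("afast_sic", 2 * n), slope("afast_sic", n))
  expect_identical(update_flops("epoic", N, n, m), update_flops("epoic", N, n, 4 * m))
  # the family ordering at generic-fitting sizes: SIC >> Fast-SIC >
  # aFast-SIC > POIC = E-POIC
  v <- vapply(c("sic", "fast_sic", "afast_sic", "poic"), function(a)
    update_flops(a, N, n, m), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_identical(update_flops("poic", N, n, m), update_flops("epoic", N, n, m))
  # descriptor channels multiply every per-pixel term
  expect_equal(update_flops("poic", N, n, m, C = 8) - n^3,
               8 * (update_flops("poic", N, n, m) - n^3))
})
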