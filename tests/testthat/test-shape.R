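test_that("Procrustes alignment is a fixed point on identical shapes and removes similarity exactly", {
  sh <- random_shapes(1, 8, seed = 3)[[1]]
  res <- procrustes_align(list(sh, sh, sh))
  for (a in res$aligned) expect_equal(a, res$aligned[[1]], tolerance = 1e-12)
  # the mean equals the aligned shapes up to the unit-norm convention
  expect_equal(res$mean / sqrt(sum(res$mean^2)), res$mean, tolerance = 1e-12)
  expect_lt(max(abs(res$aligned[[1]] - res$mean * sqrt(sum(res$aligned[[1]]^2)))), 1e-8)

  # a rotated and scaled copy aligns exactly onto the original
  M <- lmk_matrix(sh)
  R90 <- matrix(c(0, -1, 1, 0), 2, 2)
  sh2 <- lmk_vector(3 * M %*% R90)
  res2 <- procrustes_align(list(sh, sh2))
  expect_lt(max(abs(res2$aligned[[1]] - res2$aligned[[2]])), 1e-8)
})

test_that("Procrustes mean is invariant to the input ordering and idempotent", {
  shapes <- random_shapes(10, 7, seed = 11)
  r1 <- procrustes_align(shapes)
  r2 <- procrustes_align(rev(shapes))
  expect_lt(max(abs(r1$mean - r2$mean)), 1e-9)
  # aligning already-aligned shapes changes nothing
  r3 <- procrustes_align(r1$aligned)
  for (i in seq_along(shapes)) {
    expect_lt(max(abs(r3$aligned[[i]] - r1$aligned[[i]] / sqrt(sum(r1$aligned[[i]]^2)) *
                        sqrt(sum(r3$aligned[[i]]^2)))), 1e-7)
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  sh <- random_shapes(1, 6)[[1]]
  expect_error(procrustes_align(list(sh, rep(1, 12))), "zero scale")
  expect_error(procrustes_align(list(sh, sh[1:10])), "expected")
  expect_error(procrustes_align(list(sh)), "at least 2")
})

test_that("shape model basis is orthonormal and the forced rank is recovered", {
  shapes <- random_shapes(12, 8, seed = 5)
  al <- procrustes_align(shapes)$aligned
  sm <- build_shape_model(al, 4)
  expect_lt(max(abs(crossprod(sm$S) - diag(sm$n))), 1e-10)
  expect_equal(sm$n, 8L)
  expect_error(build_shape_model(al, 30), "too large")

  # shapes drawn exactly from a rank-2 model: exactly 2 non-negligible
  # PCA eigenvalues
  set.seed(8)
  u <- 7L
  s0 <- random_shapes(1, u, sd = 0)[[1]]
  sim <- gnaam:::similarity_basis(s0)
  B <- rand_orthonormal(2 * u, 2)
  B <- qr.Q(qr(B - sim %*% crossprod(sim, B)))
  shapes2 <- lapply(1:10, function(i) drop(s0 + B %*% rnorm(2, sd = 0.3)))
  sm2 <- build_shape_model(shapes2, 2)
  X <- do.call(rbind, shapes2)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- svd(Xc)$d^2 / 9
  expect_gt(ev[2], 1e-8)
  expect_lt(ev[3], 1e-10)
})

test_that("PCA block matches a dense covariance eigendecomposition on a small fixture", {
  # deformations orthogonal to the similarity block by construction, so the
  # augmented PCA block spans the same subspace as the covariance's top
  # eigenvectors
  set.seed(21)
  u <- 6L
  s0 <- random_shapes(1, u, sd = 0)[[1]]
  sim <- gnaam:::similarity_basis(s0)
  B <- matrix(rnorm(2 * u * 3), 2 * u, 3)
  B <- qr.Q(qr(B - sim %*% crossprod(sim, B)))
  # coefficients centered so the sample mean is exactly s0 (keeps the
  # similarity block of the built model identical to sim)
  P <- scale(matrix(rnorm(8 * 3), 8, 3), center = TRUE, scale = FALSE)
  P <- sweep(P, 2, c(1, 0.7, 0.4), `*`)
  shapes <- lapply(1:8, function(i) drop(s0 + B %*% P[i, ]))
  sm <- build_shape_model(shapes, 3)
  X <- do.call(rbind, shapes)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / 7
  eg <- eigen(C, symmetric = TRUE)
  ang <- principal_angles(sm$S[, 5:7], eg$vectors[, 1:3])
  expect_lt(max(ang), 1e-8)
})

test_that("shape instances, projection and the translational Jacobian agree with direct evaluation", {
  sm <- small_world()$shape
  expect_equal(shape_instance(sm, rep(0, sm$n)), sm$s0)
  expect_equal(project_shape(sm, sm$s0), rep(0, sm$n))
  set.seed(2)
  p <- rnorm(sm$n)
  expect_lt(max(abs(project_shape(sm, shape_instance(sm, p)) - p)), 1e-10)
  expect_error(shape_instance(sm, p[-1]), "length")

  # direct substitution on a hand-built 2-point model
  m2 <- gnaam:::shape_model_from_basis(c(0, 0, 1, 0),
                                       matrix(c(0, 0, 0, 1), 4, 1), 1, n_sim = 0L)
  expect_equal(shape_instance(m2, 2), c(0, 0, 1, 2))
  tj <- translational_shape_jacobian(m2)
  expect_equal(tj[[1]], matrix(0, 2, 1))
  expect_equal(tj[[2]], matrix(c(0, 1), 2, 1))

  # residual orthogonal to the basis: projection returns p, residual norm
  # preserved
  r <- rnorm(2 * sm$u)
  r <- r - sm$S %*% crossprod(sm$S, r)
  s <- drop(sm$s0 + sm$S %*% p + r)
  expect_lt(max(abs(project_shape(sm, s) - p)), 1e-10)
  expect_equal(sqrt(sum((s - shape_instance(sm, project_shape(sm, s)))^2)),
               sqrt(sum(r^2)), tolerance = 1e-10)

  # linearity (exact): s(a p1 + b p2) = a s(p1) + b s(p2) - (a+b-1) s0
  p2 <- rnorm(sm$n)
  a <- 0.7; b <- -1.3
  expect_equal(shape_instance(sm, a * p + b * p2),
               a * shape_instance(sm, p) + b * shape_instance(sm, p2) - (a + b - 1) * sm$s0,
               tolerance = 1e-12)
})

test_that("translational Jacobian matches finite differences and re-stacks to a row permutation of S", {
  sm <- small_world()$shape
  tj <- translational_shape_jacobian(sm)
  h <- 1e-6
  for (j in c(1L, sm$n)) {
    dp <- rep(0, sm$n); dp[j] <- h
    fd <- (shape_instance(sm, dp) - shape_instance(sm, -dp)) / (2 * h)
    for (k in seq_len(sm$u)) {
      expect_lt(max(abs(tj[[k]][, j] - fd[c(2 * k - 1, 2 * k)])), 1e-6)
    }
  }
  stacked <- do.call(rbind, tj)
  perm <- as.vector(rbind(seq(1, 2 * sm$u, 2), seq(2, 2 * sm$u, 2)))
  expect_equal(stacked, sm$S[perm, ], tolerance = 1e-14)
})
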