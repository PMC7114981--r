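# Weighted least-squares fitting on a sparse sample grid. The weight matrix
# is a binary diagonal selecting the evaluated sample positions; it is never
# materialized — only the kept rows of each matrix are formed.

#' Sparse sample grid over a reference frame
#'
#' Keeps every `stride`-th pixel in x and y of the reference mask (the
#' default stride of 2 keeps about a quarter of the pixels); all channels of
#' a kept pixel are kept.
#'
#' @param frame a `ref_frame`.
#' @param C channel count of the appearance model (default 1).
#' @param stride subsampling stride in pixels (default 2).
#' @return object of class `sample_weights`: list with `keep_pixels`
#'   (logical over the N mask pixels), `keep` (logical over the N*C sample
#'   positions), `N_w` (kept pixel count), `N`, `C`.
#' @export
make_sparse_grid <- function(frame, C = 1L, stride = 2L) {
  x0 <- frame$bbox[["xmin"]]; y0 <- frame$bbox[["ymin"]]
  kp <- ((frame$mask[, 1L] - x0) %% stride == 0L) &
    ((frame$mask[, 2L] - y0) %% stride == 0L)
  keep <- rep(kp, each = C)
  structure(list(keep_pixels = kp, keep = keep,
                 N_w = sum(kp), N = frame$N, C = as.integer(C)),
            class = "sample_weights")
}

#' Sample weights from an explicit logical vector
#'
#' @param keep logical vector over the N*C sample positions.
#' @param C channel count.
#' @return a `sample_weights` object.
#' @export
sample_weights_from_logical <- function(keep, C = 1L) {
  kp <- keep[seq(1L, length(keep), by = C)]
  structure(list(keep_pixels = kp, keep = keep,
                 N_w = sum(kp), N = length(keep) / C, C = as.integer(C)),
            class = "sample_weights")
}

#' Scalars sampled per iteration under a weighting scheme
#'
#' The bookkeeping quantity behind the sparse-grid trade-off: a model with C
#' channels evaluated on `N_w` kept pixels touches `N_w * C` scalars per
#' residual evaluation (against `N` for a full-grid single-channel model).
#'
#' @param weights a `sample_weights` object, or NULL for the full grid.
#' @param N full mask pixel count (used when `weights` is NULL).
#' @param C channel count (used when `weights` is NULL).
#' @return integer scalar count.
#' @export
sampled_scalar_count <- function(weights = NULL, N = NULL, C = 1L) {
  if (is.null(weights)) return(as.integer(N * C))
  as.integer(weights$N_w * weights$C)
}

#' Weighted Gauss-Newton update on a sparse grid
#'
#' Solves the weighted least-squares problem obtained by restricting the
#' residual to the kept sample positions. Because the weights are binary,
#' each weighted matrix is just the kept rows of its full counterpart; the
#' diagonal weight matrix is never formed. On the subset the appearance
#' basis is no longer orthonormal, so the general Gram-matrix forms are
#' used: `dc = (A_w^T A_w)^-1 A_w^T (r_w - J_w dp)` and
#' `dp = H_w^-1 J_pw^T r_w` with `J_pw = P_w J_w`. With all-ones weights the
#' unweighted update applies unchanged (no subsetting), so the call is
#' dispatched to the corresponding unweighted rule.
#'
#' @param residual0 full-length residual: `I[p] - A0` for
#'   `fast_sic`/`afast_sic`/`poic`/`epoic_v1`, `I[p] - A0 - A c` for `sic`.
#' @param J full combined Jacobian `J(c)` (for `poic`/`epoic_v1`, pass
#'   `J_0`).
#' @param basis projection subspace: the appearance basis `A` (or `A_phi`
#'   for `epoic_v1`). May have non-orthonormal columns.
#' @param c current appearance coefficients (ignored by project-out rules).
#' @param weights a `sample_weights` object.
#' @param algorithm one of `"sic"`, `"fast_sic"`, `"afast_sic"`, `"poic"`,
#'   `"epoic_v1"`.
#' @return list with `dp` and, for simultaneous rules, `dc`.
#' @export
weighted_update <- function(residual0, J, basis, c = rep(0, ncol(basis)),
                            weights,
                            algorithm = c("fast_sic", "afast_sic", "sic",
                                          "poic", "epoic_v1")) {
  algorithm <- match.arg(algorithm)
  m <- ncol(basis)
  n <- ncol(J)
  if (weights$N_w * weights$C < n + m) {
    stop(sprintf("under-determined sparse-grid system: N_w = %d kept pixels for n = %d, m = %d",
                 weights$N_w, n, m), call. = FALSE)
  }
  if (all(weights$keep)) {
    # W = E: the unweighted (orthonormal-basis) update applies exactly
    return(switch(algorithm,
      sic = sic_update(residual0, J, basis),
      fast_sic = fast_sic_update(residual0, J, basis, c),
      afast_sic = afast_sic_update(residual0, J, basis, c),
      poic = poic_update(residual0, poic_precompute(list(J0 = J), basis)),
      epoic_v1 = {
        sv <- svd(basis, nv = 0L)
        rank <- sum(sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10)
        Q <- sv$u[, seq_len(rank), drop = FALSE]
        Jp <- J - Q %*% crossprod(Q, J)
        sol <- solve_psd(crossprod(Jp), crossprod(Jp, residual0))
        list(dp = as.vector(sol), rcond = attr(sol, "rcond"))
      }))
  }
  rows <- which(weights$keep)
  As <- basis[rows, , drop = FALSE]
  Js <- J[rows, , drop = FALSE]
  rs <- residual0[rows]
  G <- crossprod(As)
  proj_w <- function(X) {
    if (m == 0L) return(X)
    X - As %*% solve_psd(G, crossprod(As, X))
  }
  if (algorithm == "sic") {
    Jstack <- cbind(As, Js)
    sol <- solve_psd(crossprod(Jstack), crossprod(Jstack, rs))
    v <- as.vector(sol)
    return(list(dp = v[-seq_len(m)], dc = v[seq_len(m)]))
  }
  if (algorithm == "afast_sic") {
    pr <- proj_w(rs)
    sol <- solve_psd(crossprod(Js), crossprod(Js, pr))
    dp <- as.vector(sol)
    dc <- if (m > 0L) as.vector(solve_psd(G, crossprod(As, rs - Js %*% dp))) - c else numeric(0)
    return(list(dp = dp, dc = dc))
  }
  Jp <- proj_w(Js)
  sol <- solve_psd(crossprod(Jp), crossprod(Jp, rs))
  dp <- as.vector(sol)
  if (algorithm %in% c("poic", "epoic_v1")) return(list(dp = dp))
  dc <- if (m > 0L) as.vector(solve_psd(G, crossprod(As, rs - Js %*% dp))) - c else numeric(0)
  list(dp = dp, dc = dc)
}
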