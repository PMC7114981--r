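# Gauss-Newton update rules: SIC, Fast-SIC, aFast-SIC, POIC, the extended
# project-out family (E-POIC-v1, E-POIC-v2, combined E-POIC), and their
# weighted sparse-grid variants.

#' Simultaneous inverse-compositional update
#'
#' Joint Gauss-Newton step in shape and appearance: with stacked Jacobian
#' `J_sic = [A J]` and Hessian `H_sic = J_sic^T J_sic`, the update is
#' `[dc; dp] = H_sic^-1 J_sic^T r` for residual `r = I[p] - A0 - A c`.
#' Near-singular Hessians fall back to a small ridge with a warning.
#'
#' @param residual sample-space residual `I[p] - A0 - A c`.
#' @param J combined Jacobian `J(c) = J_0 + sum_i c_i J_i` (NC x n).
#' @param A appearance basis (NC x m, orthonormal).
#' @return list with `dp`, `dc` and `rcond` of the solved Hessian.
#' @export
sic_update <- function(residual, J, A) {
  m <- ncol(A)
  Js <- cbind(A, J)
  H <- crossprod(Js)
  sol <- solve_psd(H, crossprod(Js, residual))
  v <- as.vector(sol)
  list(dp = v[-seq_len(m)], dc = v[seq_len(m)],
       rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}

#' Fast-SIC update
#'
#' Produces exactly the SIC step by block elimination: the shape step solves
#' the residual in the orthogonal complement of the appearance subspace,
#' `dp = (J_f^T J_f)^-1 J_f^T (I - A0)` with `J_f = P_A J`, and the
#' appearance step back-substitutes `dc = A^T (I - A0 - A c - J dp)`.
#'
#' @param residual0 `I[p] - A0` (note: not the c-corrected residual).
#' @param J combined Jacobian `J(c)`.
#' @param A orthonormal appearance basis.
#' @param c current appearance coefficients (defaults to zeros).
#' @return list with `dp`, `dc`, `rcond`.
#' @export
fast_sic_update <- function(residual0, J, A, c = rep(0, ncol(A))) {
  Jf <- if (ncol(A) > 0L) J - A %*% crossprod(A, J) else J
  sol <- solve_psd(crossprod(Jf), crossprod(Jf, residual0))
  dp <- as.vector(sol)
  dc <- if (ncol(A) > 0L) drop(crossprod(A, residual0 - J %*% dp)) - c else numeric(0)
  list(dp = dp, dc = dc, rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}

#' Approximate Fast-SIC update
#'
#' One sweep of block coordinate descent: the shape Hessian is approximated
#' by the unprojected `J^T J`, so `dp = (J^T J)^-1 J^T P_A (I - A0)`, while
#' `dc` back-substitutes exactly as in Fast-SIC. Dominant cost drops from
#' O(nmN) to O((n+m)N) per iteration.
#'
#' @inheritParams fast_sic_update
#' @return list with `dp`, `dc`, `rcond`.
#' @export
afast_sic_update <- function(residual0, J, A, c = rep(0, ncol(A))) {
  pr <- if (ncol(A) > 0L) residual0 - A %*% crossprod(A, residual0) else residual0
  sol <- solve_psd(crossprod(J), crossprod(J, pr))
  dp <- as.vector(sol)
  dc <- if (ncol(A) > 0L) drop(crossprod(A, residual0 - J %*% dp)) - c else numeric(0)
  list(dp = dp, dc = dc, rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}

#' Precompute the project-out (POIC) fitter state
#'
#' `J_poic = P_A J_0` and `H_poic = J_poic^T J_poic` are both fixed across
#' iterations, which is what makes POIC O(nN) per iteration.
#'
#' @param sds an `sds_set` (only `J0` is used).
#' @param A orthonormal appearance basis.
#' @return list with `J_poic`, `H_poic`.
#' @export
poic_precompute <- function(sds, A) {
  J0 <- sds$J0
  Jp <- if (ncol(A) > 0L) J0 - A %*% crossprod(A, J0) else J0
  list(J_poic = Jp, H_poic = crossprod(Jp))
}

#' POIC update
#'
#' `dp = H_poic^-1 J_poic^T (I[p] - A0)` with the precomputed projected-out
#' Jacobian and Hessian.
#'
#' @param residual0 `I[p] - A0`.
#' @param state list from [poic_precompute()].
#' @return list with `dp`, `rcond`.
#' @export
poic_update <- function(residual0, state) {
  sol <- solve_psd(state$H_poic, crossprod(state$J_poic, residual0))
  list(dp = as.vector(sol), rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}

#' Build the extended appearance-plus-steepest-descent subspace
#'
#' For each shape direction j, the per-basis steepest-descent columns
#' `J_i^j, i = 1..m` span the directions that the combined Jacobian's j-th
#' column can take as the appearance coefficients vary. Each direction gets
#' its own subspace `Phi_j` (top principal components of those columns), and
#' the extended subspace is `A_Phi = [A, Phi_1, ..., Phi_n]`. The returned
#' projector applies `P_Phi = E - A_Phi (A_Phi^T A_Phi)^-1 A_Phi^T`
#' matrix-free via an internal orthonormal basis of the column span (so rank
#' deficiency of the concatenation is handled by dropping null directions).
#'
#' @param A orthonormal appearance basis.
#' @param sds an `sds_set` with the per-basis steepest-descent images.
#' @param l_total total number of Phi components, split evenly across the n
#'   shape directions (capped at the available rank per direction, with a
#'   warning if fewer components exist than requested).
#' @return list with `Phi` (N x (<= l_total)), `A_phi`, `Q` (orthonormal
#'   span basis) and `projector` (a `projector` applying `P_Phi`).
#' @export
build_extended_subspace <- function(A, sds, l_total) {
  n <- sds$n
  m <- length(sds$Ji)
  l_per <- max(1L, floor(l_total / n))
  Phi_blocks <- vector("list", n)
  short <- FALSE
  for (j in seq_len(n)) {
    Mj <- vapply(sds$Ji, function(Ji) Ji[, j], numeric(nrow(sds$J0)))
    if (m == 0L) { Phi_blocks[[j]] <- NULL; next }
    sv <- svd(Mj, nv = 0L)
    rank <- sum(sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10)
    keep <- min(l_per, rank)
    if (keep < l_per) short <- TRUE
    Phi_blocks[[j]] <- sv$u[, seq_len(keep), drop = FALSE]
  }
  Phi <- do.call(cbind, Phi_blocks)
  if (is.null(Phi)) Phi <- matrix(0, nrow(sds$J0), 0L)
  if (short) warning("rank-deficient steepest-descent collection: kept fewer Phi components than requested", call. = FALSE)
  A_phi <- cbind(A, Phi)
  if (ncol(A_phi) > 0L) {
    sv <- svd(A_phi, nv = 0L)
    rank <- sum(sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-10)
    Q <- sv$u[, seq_len(rank), drop = FALSE]
  } else {
    Q <- matrix(0, nrow(sds$J0), 0L)
  }
  ap <- function(X) if (ncol(Q) == 0L) X else X - Q %*% crossprod(Q, X)
  structure(list(Phi = Phi, A_phi = A_phi, Q = Q,
                 projector = structure(list(apply = ap, A = Q), class = "projector")),
            class = "extended_subspace")
}

#' Precompute the E-POIC-v1 fitter state
#'
#' POIC with `P_A` replaced by the extended projector `P_Phi`:
#' `J = P_Phi J_0`, `H = J^T J`, both fixed across iterations.
#'
#' @param sds an `sds_set`.
#' @param ext an `extended_subspace` from [build_extended_subspace()].
#' @return list with `J_epoic`, `H_epoic`.
#' @export
epoic_v1_precompute <- function(sds, ext) {
  Jp <- ext$projector$apply(sds$J0)
  list(J_epoic = Jp, H_epoic = crossprod(Jp))
}

#' E-POIC-v1 update
#'
#' @param residual0 `I[p] - A0`.
#' @param state list from [epoic_v1_precompute()].
#' @return list with `dp`, `rcond`.
#' @export
epoic_v1_update <- function(residual0, state) {
  sol <- solve_psd(state$H_epoic, crossprod(state$J_epoic, residual0))
  list(dp = as.vector(sol), rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}

#' Precompute the E-POIC-v2 (project-out joint alignment) state
#'
#' From the training images' reference-frame Jacobians `G_i`:
#' `J_ja = P_A sum_i G_i` (equal to `P_A J_0` up to the sum-vs-mean factor,
#' since the gradient operator is linear) and the joint-alignment Hessian
#' `H_ja = sum_i G_i^T P_A G_i`, which drops the cross-terms
#' `G_i^T P_A G_j (i != j)` present in the POIC Hessian of the summed
#' Jacobian.
#'
#' @param G_list list of D training-image Jacobians (NC x n each).
#' @param A orthonormal appearance basis (or a `projector`).
#' @return list with `J_ja`, `H_ja`.
#' @export
epoic_v2_precompute <- function(G_list, A) {
  proj <- if (inherits(A, "projector")) A else build_projector(A)
  Gsum <- Reduce(`+`, G_list)
  J_ja <- proj$apply(Gsum)
  H_ja <- matrix(0, ncol(Gsum), ncol(Gsum))
  for (G in G_list) {
    PG <- proj$apply(G)
    H_ja <- H_ja + crossprod(PG)  # G^T P G = (PG)^T (PG): symmetric PSD
  }
  list(J_ja = J_ja, H_ja = H_ja)
}

#' E-POIC-v2 update
#'
#' `dp = H_ja^-1 J_ja^T (I[p] - A0)`.
#'
#' @param residual0 `I[p] - A0`.
#' @param state list from [epoic_v2_precompute()].
#' @return list with `dp`, `rcond`.
#' @export
epoic_v2_update <- function(residual0, state) {
  sol <- solve_psd(state$H_ja, crossprod(state$J_ja, residual0))
  list(dp = as.vector(sol), rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}

#' Precompute the combined E-POIC state
#'
#' The joint-alignment formulation of E-POIC-v2 with `P_A` replaced by the
#' extended projector `P_Phi`: `J = P_Phi sum_i G_i`,
#' `H = sum_i G_i^T P_Phi G_i`. Only one NC x n matrix is needed at fit
#' time.
#'
#' @param G_list list of training-image Jacobians.
#' @param ext an `extended_subspace` (or any `projector`).
#' @return list with `J_epoic`, `H_epoic`.
#' @export
epoic_precompute <- function(G_list, ext) {
  proj <- if (inherits(ext, "extended_subspace")) ext$projector else ext
  st <- epoic_v2_precompute(G_list, proj)
  list(J_epoic = st$J_ja, H_epoic = st$H_ja)
}

#' Combined E-POIC update
#'
#' @param residual0 `I[p] - A0`.
#' @param state list from [epoic_precompute()].
#' @return list with `dp`, `rcond`.
#' @export
epoic_update <- function(residual0, state) {
  sol <- solve_psd(state$H_epoic, crossprod(state$J_epoic, residual0))
  list(dp = as.vector(sol), rcond = attr(sol, "rcond"), ridged = attr(sol, "ridged"))
}
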