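# Evaluation: normalized point-to-point error, cumulative error
# distribution curves, and the shape-model Oracle baseline.

#' Face size of a landmark set
#'
#' Geometric mean of the bounding-box width and height. An
#' `"interocular"`-style alternative (distance between two chosen landmark
#' indices) is available via `ref_points`.
#'
#' @param landmarks landmark vector.
#' @param ref_points optional pair of landmark indices; when given, the
#'   distance between those two landmarks is returned instead.
#' @return positive scalar.
#' @export
face_size <- function(landmarks, ref_points = NULL) {
  M <- lmk_matrix(landmarks)
  if (!is.null(ref_points)) {
    return(sqrt(sum((M[ref_points[1L], ] - M[ref_points[2L], ])^2)))
  }
  sqrt(diff(range(M[, 1L])) * diff(range(M[, 2L])))
}

#' Normalized point-to-point landmark error
#'
#' Mean over landmarks of the Euclidean distance between fitted and
#' ground-truth positions, divided by the face size.
#'
#' @param fit fitted landmark vector.
#' @param gt ground-truth landmark vector (same u).
#' @param face_size normalizing length; defaults to [face_size()] of the
#'   ground truth.
#' @return non-negative scalar.
#' @export
normalized_pt_pt_error <- function(fit, gt, face_size = NULL) {
  if (length(fit) != length(gt)) stop("landmark counts differ", call. = FALSE)
  if (is.null(face_size)) face_size <- gnaam::face_size(gt)
  if (face_size <= 0) stop("face size must be positive", call. = FALSE)
  F <- lmk_matrix(fit); G <- lmk_matrix(gt)
  mean(sqrt(rowSums((F - G)^2))) / face_size
}

#' Cumulative error distribution curve
#'
#' Fraction of images with error below each threshold.
#'
#' @param errors vector of per-image errors.
#' @param thresholds threshold grid.
#' @return data.frame with columns `threshold` and `fraction`
#'   (non-decreasing, in [0, 1]).
#' @export
ced_curve <- function(errors, thresholds) {
  stopifnot(all(errors >= 0))
  data.frame(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(errors < t), numeric(1))
  )
}

#' Oracle baseline: best shape-model reconstruction of the ground truth
#'
#' Similarity-aligns the ground-truth landmarks into the model frame,
#' projects onto the shape basis, reconstructs, and maps back — the best fit
#' any algorithm using this shape model could achieve.
#'
#' @param model a `shape_model`.
#' @param gt ground-truth landmark vector.
#' @return reconstructed landmark vector.
#' @export
oracle_baseline <- function(model, gt) {
  sim <- similarity_to_reference(gt, model$s0)
  G <- lmk_matrix(gt)
  aligned <- sweep(sim$s * G %*% t(sim$R), 2L, sim$t, `+`)
  p <- project_shape(model, lmk_vector(aligned))
  rec <- lmk_matrix(shape_instance(model, p))
  back <- sweep(rec, 2L, sim$t) %*% sim$R / sim$s
  lmk_vector(back)
}
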