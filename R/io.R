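# File formats: PTS landmark files, PNG images, and the model container.

#' Read a PTS landmark file
#'
#' The face-alignment standard format: a `version: 1` header, an `n_points`
#' count, and a brace-delimited list of `x y` lines. Coordinates are 1-based
#' on disk and converted to 0-based in memory.
#'
#' @param path file path.
#' @return landmark vector (interleaved, 0-based).
#' @export
read_pts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  npl <- grep("^n_points\\s*:", lines)
  if (length(npl) != 1L) stop(sprintf("%s: missing n_points header", path), call. = FALSE)
  u <- as.integer(sub("^n_points\\s*:\\s*", "", lines[npl]))
  open <- which(lines == "{"); close <- which(lines == "}")
  if (length(open) != 1L || length(close) != 1L || close < open) {
    stop(sprintf("%s: missing braces", path), call. = FALSE)
  }
  body <- lines[(open + 1L):(close - 1L)]
  body <- body[nzchar(body)]
  if (length(body) != u) {
    stop(sprintf("%s: n_points = %d but %d coordinate lines (line %d)",
                 path, u, length(body), open + 1L), call. = FALSE)
  }
  coords <- t(vapply(strsplit(body, "\\s+"), function(x) as.numeric(x[1:2]), numeric(2)))
  if (any(!is.finite(coords))) stop(sprintf("%s: malformed coordinates", path), call. = FALSE)
  lmk_vector(coords - 1)
}

#' Write a PTS landmark file
#'
#' Inverse of [read_pts()]: coordinates are written 1-based with enough
#' digits for a lossless round-trip at printed precision.
#'
#' @param landmarks landmark vector (0-based).
#' @param path output path.
#' @export
write_pts <- function(landmarks, path) {
  M <- lmk_matrix(landmarks) + 1
  lines <- c(
    "version: 1",
    sprintf("n_points: %d", nrow(M)),
    "{",
    sprintf("%.10g %.10g", M[, 1L], M[, 2L]),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an image as a grayscale matrix or multi-channel array
#'
#' PNG input via the `png` package. Color images are converted to luminance
#' (Rec. 709 weights) unless `gray = FALSE`.
#'
#' @param path file path (PNG).
#' @param gray collapse color channels to luminance (default TRUE).
#' @return matrix (grayscale) or H x W x C array, values in [0, 1].
#' @export
read_image <- function(path, gray = TRUE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L || !gray) return(img)
  C <- dim(img)[3L]
  if (C >= 3L) {
    0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
  } else {
    img[, , 1L]
  }
}

#' Save a trained model container
#'
#' Serializes the model (shape model, per-level frames, appearance models,
#' steepest-descent images and fitter precomputations) as a single
#' named-array container via R's native serialization; the round-trip is
#' bitwise exact.
#'
#' @param model a `gnaam_model` (or any model object from this package).
#' @param path output path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(container_version = 1L, model = model), path)
  invisible(path)
}

#' Load a model container saved by [save_model()]
#'
#' @param path file path.
#' @return the stored model object.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$container_version)) {
    stop("not a gnaam model container", call. = FALSE)
  }
  if (obj$container_version != 1L) {
    stop(sprintf("unsupported container version %s", obj$container_version), call. = FALSE)
  }
  obj$model
}
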