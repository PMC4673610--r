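#' Similarity transform (scale + rotation + translation)
#'
#' Maps 0-based pixel coordinates `p = (x, y)` of one frame into another:
#' `p' = s * R(theta) * p + t`, with `R` the rotation matrix in the display
#' convention (y down, `theta` in degrees, counter-clockwise positive on
#' screen): `R = [cos sin; -sin cos]`.
#'
#' @param scale scale factor `s > 0`.
#' @param rotation_deg rotation angle in degrees.
#' @param t translation `(tx, ty)` in target-frame pixels.
#' @return object of class `SimilarityTransform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0, t = c(0, 0)) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    stop("`scale` must be a single finite positive number", call. = FALSE)
  if (!is.numeric(rotation_deg) || length(rotation_deg) != 1 ||
      !is.finite(rotation_deg))
    stop("`rotation_deg` must be a single finite number", call. = FALSE)
  if (!is.numeric(t) || length(t) != 2 || !all(is.finite(t)))
    stop("`t` must be two finite numbers (tx, ty)", call. = FALSE)
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 t = as.numeric(t)),
            class = "SimilarityTransform")
}

as_similarity_transform <- function(x) {
  if (inherits(x, "SimilarityTransform")) return(x)
  if (inherits(x, "AlignmentResult"))
    return(similarity_transform(1, x$rotation_deg, x$shift))
  if (is.list(x) && !is.null(x$scale)) {
    t <- if (!is.null(x$t)) x$t else c(x$tx_px, x$ty_px)
    return(similarity_transform(x$scale, x$rotation_deg, t))
  }
  stop("cannot interpret object as a similarity transform", call. = FALSE)
}

#' @export
print.SimilarityTransform <- function(x, ...) {
  cat(sprintf("<SimilarityTransform> s = %.6g, theta = %.6g deg, t = (%.6g, %.6g)\n",
              x$scale, x$rotation_deg, x$t[1], x$t[2]))
  if (!is.null(x$status)) cat("  status:", x$status, "\n")
  invisible(x)
}

# Rotation matrix in the display convention.
rot_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param pts n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_similarity <- function(transform, pts) {
  tr <- as_similarity_transform(transform)
  pts <- rbind(pts)
  out <- tr$scale * (pts %*% t(rot_mat(tr$rotation_deg)))
  out[, 1] <- out[, 1] + tr$t[1]
  out[, 2] <- out[, 2] + tr$t[2]
  out
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @return the inverse transform; composing the two is the identity to
#'   better than 1e-9.
#' @export
invert_similarity <- function(transform) {
  tr <- as_similarity_transform(transform)
  s <- 1 / tr$scale
  R <- rot_mat(-tr$rotation_deg)
  t_new <- -s * as.vector(R %*% tr$t)
  similarity_transform(s, -tr$rotation_deg, t_new)
}

#' Compose two similarity transforms (`b` applied first, then `a`)
#' @param a,b [similarity_transform()] objects.
#' @return the composition `a o b`.
#' @export
compose_similarity <- function(a, b) {
  a <- as_similarity_transform(a); b <- as_similarity_transform(b)
  s <- a$scale * b$scale
  th <- a$rotation_deg + b$rotation_deg
  t_new <- a$scale * as.vector(rot_mat(a$rotation_deg) %*% b$t) + a$t
  similarity_transform(s, th, t_new)
}
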