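#' Match keypoint descriptors between two sets
#'
#' Nearest-neighbour matching by Euclidean descriptor distance with Lowe's
#' ratio test (`d1/d2 < ratio` against the second-nearest neighbour) and
#' mutual-best filtering, which enforces a one-to-one match set.
#'
#' @param query,reference `Keypoints` objects (non-empty).
#' @param ratio ratio-test threshold in (0, 1].
#' @return `data.frame` with `query_idx`, `ref_idx`, `distance`; empty when
#'   nothing survives the tests.
#' @export
match_descriptors <- function(query, reference, ratio = 0.8) {
  if (!inherits(query, "Keypoints") || !inherits(reference, "Keypoints"))
    stop("`query` and `reference` must be Keypoints objects", call. = FALSE)
  nq <- nrow(query$table); nr <- nrow(reference$table)
  if (nq == 0 || nr == 0)
    stop("keypoint sets must be non-empty", call. = FALSE)
  if (ratio <= 0 || ratio > 1)
    stop("`ratio` must be in (0, 1]", call. = FALSE)
  # unit-norm rows: d^2 = 2 - 2 q.r
  G <- query$desc %*% t(reference$desc)
  D2 <- pmax(2 - 2 * G, 0)
  best <- apply(D2, 1, which.min)
  d1 <- sqrt(D2[cbind(seq_len(nq), best)])
  d2 <- if (nr >= 2) {
    sqrt(vapply(seq_len(nq), function(i) {
      v <- D2[i, ]; v[best[i]] <- Inf; min(v)
    }, numeric(1)))
  } else rep(Inf, nq)
  pass <- ifelse(is.finite(d2), d1 / pmax(d2, 1e-12) < ratio, d1 < 0.5)
  # mutual best
  rbest <- apply(D2, 2, which.min)
  mutual <- rbest[best] == seq_len(nq)
  keep <- which(pass & mutual)
  data.frame(query_idx = keep, ref_idx = best[keep], distance = d1[keep])
}

# closed-form similarity through two correspondences (complex formulation)
similarity_from_two <- function(p, q) {
  zp <- complex(real = p[, 1], imaginary = p[, 2])
  zq <- complex(real = q[, 1], imaginary = q[, 2])
  dzp <- zp[2] - zp[1]
  if (Mod(dzp) < 1e-12) return(NULL)
  a <- (zq[2] - zq[1]) / dzp
  b <- zq[1] - a * zp[1]
  list(a = a, b = b)
}

# least-squares similarity over n >= 2 correspondences
similarity_lsq <- function(p, q) {
  zp <- complex(real = p[, 1], imaginary = p[, 2])
  zq <- complex(real = q[, 1], imaginary = q[, 2])
  mp <- mean(zp); mq <- mean(zq)
  num <- sum((zq - mq) * Conj(zp - mp))
  den <- sum(Mod(zp - mp)^2)
  if (den < 1e-12) return(NULL)
  a <- num / den
  b <- mq - a * mp
  list(a = a, b = b)
}

ab_to_transform <- function(ab) {
  s <- Mod(ab$a)
  # display convention: y down, screen-CCW positive angle
  theta <- -Arg(ab$a) * 180 / pi
  similarity_transform(scale = s, rotation_deg = theta,
                       t = c(Re(ab$b), Im(ab$b)))
}

reproj_error <- function(ab, p, q) {
  zp <- complex(real = p[, 1], imaginary = p[, 2])
  zq <- complex(real = q[, 1], imaginary = q[, 2])
  Mod(ab$a * zp + ab$b - zq)
}

#' Robust similarity-transform estimation from correspondences
#'
#' Random-sample consensus on the closed-form two-point similarity:
#' repeatedly sample two correspondences, solve for scale/rotation/
#' translation, count inliers by reprojection error, then refit by least
#' squares on the largest inlier set (with one re-classification pass).
#' The iteration count (25) gives 99.9% success at an assumed 50% inlier
#' rate; when the number of point pairs is small, all pairs are tried
#' exhaustively instead.
#'
#' @param p,q n x 2 matrices of corresponding (x, y) points (`p` in the
#'   query frame, `q` in the reference frame); n >= 2.
#' @param inlier_tol_px reprojection-error tolerance in reference pixels.
#' @param min_inliers minimum consensus size for status `"located"`.
#' @param seed RNG seed for the sampling.
#' @return list with `transform` ([similarity_transform()] mapping `p`
#'   into `q` coordinates), `inliers` (logical vector), `inlier_count`,
#'   `status` (`"located"`, `"ambiguous"` or `"failed"`).
#' @export
estimate_similarity <- function(p, q, inlier_tol_px = 3, min_inliers = 8,
                                seed = 0) {
  p <- rbind(p); q <- rbind(q)
  n <- nrow(p)
  if (n < 2 || nrow(q) != n)
    stop("need at least 2 corresponding point pairs", call. = FALSE)
  pairs <- if (choose(n, 2) <= 300) {
    idx <- t(utils::combn(n, 2))
    split(idx, seq_len(nrow(idx)))
  } else {
    with_seed(seed, lapply(seq_len(25), function(i) sample.int(n, 2)))
  }
  best_inl <- rep(FALSE, n); best_cnt <- 0
  for (pr in pairs) {
    ab <- similarity_from_two(p[pr, , drop = FALSE], q[pr, , drop = FALSE])
    if (is.null(ab)) next
    inl <- reproj_error(ab, p, q) < inlier_tol_px
    if (sum(inl) > best_cnt) { best_cnt <- sum(inl); best_inl <- inl }
  }
  if (best_cnt < 2)
    return(list(transform = NULL, inliers = best_inl, inlier_count = 0,
                status = "failed"))
  ab <- similarity_lsq(p[best_inl, , drop = FALSE],
                       q[best_inl, , drop = FALSE])
  if (!is.null(ab)) {  # one re-classification pass, then final fit
    inl <- reproj_error(ab, p, q) < inlier_tol_px
    if (sum(inl) >= 2) {
      best_inl <- inl
      ab <- similarity_lsq(p[inl, , drop = FALSE], q[inl, , drop = FALSE])
    }
  }
  if (is.null(ab))
    return(list(transform = NULL, inliers = best_inl, inlier_count = 0,
                status = "failed"))
  cnt <- sum(best_inl)
  status <- if (cnt >= min_inliers) {
    if (cnt / n >= 0.25) "located" else "ambiguous"
  } else "failed"
  # a failed consensus asserts no transform
  list(transform = if (status == "failed") NULL else ab_to_transform(ab),
       inliers = best_inl, inlier_count = cnt, status = status)
}

#' Locate a region of interest on the global map
#'
#' Finds the similarity transform (scale, rotation, translation) that maps
#' ROI pixel coordinates onto global-map pixel coordinates by matching
#' blob keypoints detected on the two binary micro-pattern masks. Works
#' across modalities (bright-field vs back-scatter have opposite contrast;
#' masks make them comparable), under magnification changes, sample
#' rotation, and partial island loss. A low-confidence result is reported
#' as status `"failed"`, never as a transform.
#'
#' @param roi ROI image ([raster_image()], mask or matrix); segmented
#'   automatically unless already binary.
#' @param map global map (a `GlobalMap` from [stitch_grid()], image or
#'   mask).
#' @param ratio Lowe ratio for descriptor matching.
#' @param inlier_tol_px consensus tolerance in map pixels.
#' @param min_inliers minimum consensus size to accept the localisation.
#' @param seed RNG seed for the consensus sampling.
#' @param ... passed to [detect_keypoints()].
#' @return a `LocalizationResult`: list with `transform`
#'   ([similarity_transform()] ROI -> map, `NULL` unless located),
#'   `inlier_count`, `match_count`, `status`.
#' @export
locate_roi <- function(roi, map, ratio = 0.8, inlier_tol_px = 3,
                       min_inliers = 8, seed = 0, ...) {
  to_mask <- function(x) {
    if (inherits(x, "PatternMask")) return(x)
    if (inherits(x, "GlobalMap")) x <- x$image
    if (inherits(x, "RasterImage") && x$modality == "binary")
      return(pattern_mask(x$pixels > 0))
    if (is.matrix(x) && all(x %in% c(0, 1)))
      return(pattern_mask(x > 0))
    segment_pattern(x)
  }
  mroi <- to_mask(roi); mmap <- to_mask(map)
  fail <- function(m = 0L)
    structure(list(transform = NULL, inlier_count = 0L, match_count = m,
                   status = "failed"), class = "LocalizationResult")
  if (!any(mroi$mask) || !any(mmap$mask)) return(fail())
  kr <- detect_keypoints(mroi, ...)
  km <- detect_keypoints(mmap, ...)
  if (nrow(kr$table) == 0 || nrow(km$table) == 0) return(fail())
  mt <- match_descriptors(kr, km, ratio = ratio)
  if (nrow(mt) < 2) return(fail(nrow(mt)))
  est <- estimate_similarity(
    as.matrix(kr$table[mt$query_idx, c("x", "y")]),
    as.matrix(km$table[mt$ref_idx, c("x", "y")]),
    inlier_tol_px = inlier_tol_px, min_inliers = min_inliers, seed = seed)
  structure(list(transform = est$transform,
                 inlier_count = est$inlier_count,
                 match_count = nrow(mt), status = est$status),
            class = "LocalizationResult")
}

#' @export
print.LocalizationResult <- function(x, ...) {
  cat(sprintf("<LocalizationResult> status %s (%d/%d inliers)\n",
              x$status, x$inlier_count, x$match_count))
  if (!is.null(x$transform)) print(x$transform)
  invisible(x)
}

#' Augment a sparse pattern with Voronoi edges
#'
#' Voronoi tessellation of the island centroids, clipped to the image
#' frame; cell boundaries are rasterised at 1 px width and unioned with
#' the island mask. Sparse patterns gain matchable structure (edges and
#' junctions) this way, which makes keypoint localisation more robust when
#' island edges are damaged.
#'
#' @param mask pattern mask (or binary image) to augment.
#' @param islands optional `IslandTable`; computed from `mask` when `NULL`
#'   (with `min_area_px = 1`).
#' @return list with `label_map` (integer matrix, nearest-centroid cell per
#'   pixel), `edge_pixels` (`data.frame` x, y of boundary pixels),
#'   `mask_augmented` (a `PatternMask`), `n_sites`.
#' @export
voronoi_augment <- function(mask, islands = NULL) {
  m <- as_mask_matrix(mask)
  if (is.null(islands)) islands <- label_islands(m, min_area_px = 1)
  if (nrow(islands) < 1)
    stop("need at least one island centroid", call. = FALSE)
  sx <- islands$centroid_x; sy <- islands$centroid_y
  if (nrow(islands) >= 2 &&
      max(abs(sx - sx[1])) < 1e-9 && max(abs(sy - sy[1])) < 1e-9)
    stop("degenerate geometry: all centroids coincide", call. = FALSE)
  lab <- .nearest_site(nrow(m), ncol(m), sx, sy)
  if (nrow(islands) == 1) {
    return(list(label_map = lab,
                edge_pixels = data.frame(x = integer(0), y = integer(0)),
                mask_augmented = pattern_mask(m), n_sites = 1L))
  }
  # boundary = pixel whose right or lower neighbour belongs to another cell
  nr <- nrow(lab); nc <- ncol(lab)
  edge <- matrix(FALSE, nr, nc)
  edge[, -nc] <- lab[, -nc] != lab[, -1]
  edge[-nr, ] <- edge[-nr, ] | (lab[-nr, ] != lab[-1, ])
  hits <- which(edge, arr.ind = TRUE)
  aug <- m | edge
  list(label_map = lab,
       edge_pixels = data.frame(x = hits[, 2] - 1L, y = hits[, 1] - 1L),
       mask_augmented = pattern_mask(aug), n_sites = nrow(islands))
}
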