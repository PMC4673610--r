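#' Rotation + translation alignment of two micro-pattern images
#'
#' The alignment procedure for corresponding bright-field and back-scatter
#' micro-patterns: rotate one pattern against the other over the full
#' circle and register each rotated candidate by translation-only spectral
#' correlation; the angle/shift with the highest correlation peak wins. A
#' coarse sweep (default 2 deg over [0, 360)) is refined locally (default
#' 0.1 deg over +/- one coarse step). The full-circle sweep is needed
#' because specimen mounting orientation is arbitrary.
#'
#' The returned `(rotation_deg, shift)` is the transform that maps
#' `pattern_b` onto `pattern_a`: rotate `pattern_b` about its centre by
#' `rotation_deg` (counter-clockwise on screen), then translate by
#' `shift`. Ties in the score profile are broken toward the smaller angle,
#' so output is deterministic even for rotationally symmetric patterns.
#'
#' For speed, the coarse stage may run at a downsampled resolution
#' (`coarse_downsample`, default 2); the refinement always runs at full
#' resolution and the reported score/shift come from it. Profile rows are
#' tagged with their stage.
#'
#' @param pattern_a reference pattern (mask or image; binarised internally
#'   unless `use_mask = FALSE`).
#' @param pattern_b moving pattern, same scale as `pattern_a` (equalise
#'   pixel sizes upstream).
#' @param coarse_step_deg coarse sweep step, degrees.
#' @param refine_step_deg refinement step, degrees.
#' @param coarse_downsample integer downsampling factor for the coarse
#'   stage (1 = full resolution everywhere).
#' @param score_floor minimum acceptable correlation peak; below it an
#'   alignment-failed error is raised.
#' @param use_mask binarise inputs (Otsu) before aligning; set `FALSE` to
#'   correlate raw intensities.
#' @return an `AlignmentResult`: list with `rotation_deg`, `shift`
#'   (`c(dx, dy)`, integer), `score`, and `profile` (`data.frame`: angle,
#'   score, stage).
#' @export
rotational_align <- function(pattern_a, pattern_b, coarse_step_deg = 2,
                             refine_step_deg = 0.1, coarse_downsample = 2,
                             score_floor = 0.05, use_mask = TRUE) {
  get_mat <- function(x) {
    if (inherits(x, "PatternMask")) return(x$mask + 0)
    m <- as_pixel_matrix(x)
    if (!use_mask) return(m)
    if (all(m %in% c(0, 1))) m else segment_pattern(x)$mask + 0
  }
  A <- get_mat(pattern_a); B <- get_mat(pattern_b)
  if (sum(A) == 0 || sum(B) == 0)
    stop("degenerate input: empty pattern", call. = FALSE)
  if (coarse_step_deg <= 0 || refine_step_deg <= 0)
    stop("angle steps must be positive", call. = FALSE)

  sweep_scores <- function(Aref, Bmov, angles) {
    w <- taper_window(nrow(Aref), ncol(Aref), 0.1)
    am <- (Aref - mean(Aref)) * w
    pr <- next_fast_size(nrow(am)); pcn <- next_fast_size(ncol(am))
    Fa <- pc_fft(am, pr, pcn)
    cb <- c((ncol(Bmov) - 1) / 2, (nrow(Bmov) - 1) / 2)
    res <- vector("list", length(angles))
    for (i in seq_along(angles)) {
      rb <- .warp_similarity(Bmov, nrow(Aref), ncol(Aref), 1, angles[i],
                             0, 0, cb[1], cb[2], cb[1], cb[2], TRUE, 0)
      bm <- (rb - mean(rb)) * w
      Fb <- pc_fft(bm, pr, pcn)
      res[[i]] <- pc_peak(Fa, Fb, pr, pcn)
    }
    res
  }

  ds <- max(1L, as.integer(round(coarse_downsample)))
  if (ds > 1L) {
    Ac <- .resize_area(A, max(8L, nrow(A) %/% ds), max(8L, ncol(A) %/% ds))
    Bc <- .resize_area(B, max(8L, nrow(B) %/% ds), max(8L, ncol(B) %/% ds))
  } else {
    Ac <- A; Bc <- B
  }
  coarse_angles <- seq(0, 360 - coarse_step_deg, by = coarse_step_deg)
  cres <- sweep_scores(Ac, Bc, coarse_angles)
  cscores <- vapply(cres, function(r) r$score, numeric(1))
  best_c <- coarse_angles[which.max(cscores)]  # ties -> smaller angle

  refine_angles <- seq(best_c - coarse_step_deg, best_c + coarse_step_deg,
                       by = refine_step_deg)
  rres <- sweep_scores(A, B, refine_angles)
  rscores <- vapply(rres, function(r) r$score, numeric(1))
  bi <- which.max(rscores)
  best <- rres[[bi]]
  if (best$score < score_floor)
    stop("alignment failed: best correlation peak ",
         signif(best$score, 3), " below floor ", score_floor, call. = FALSE)
  profile <- rbind(
    data.frame(angle = coarse_angles, score = cscores, stage = "coarse"),
    data.frame(angle = refine_angles %% 360, score = rscores,
               stage = "refine"))
  structure(list(rotation_deg = refine_angles[bi] %% 360,
                 shift = c(best$dx, best$dy), score = best$score,
                 profile = profile),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf(
    "<AlignmentResult> theta = %.2f deg, shift = (%d, %d), score %.4f\n",
    x$rotation_deg, x$shift[1], x$shift[2], x$score))
  invisible(x)
}

#' Fuse light-microscope channels with an electron micrograph
#'
#' Transforms each light channel into electron-microscope coordinates
#' (rotation about the channel-image centre, then translation — the
#' parameters found by [rotational_align()] or a full
#' [similarity_transform()]), resampling bilinearly with zero background,
#' and stacks the result with the EM image as a multi-channel raster of
#' the EM dimensions.
#'
#' @param light_channels list of light-channel images sharing the geometry
#'   of the pattern image they were acquired with.
#' @param em_image electron micrograph defining the output frame.
#' @param result an `AlignmentResult` or [similarity_transform()] mapping
#'   light coordinates into EM coordinates.
#' @param interpolation `"bilinear"` (default) or `"nearest"` (for binary
#'   overlays).
#' @return 3-D array `(rows, cols, channels)`; light channels first, the
#'   EM image last, with channel names in `dimnames`.
#' @export
fuse_channels <- function(light_channels, em_image, result,
                          interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(light_channels, c("RasterImage", "PatternMask")) ||
      is.matrix(light_channels))
    light_channels <- list(light_channels)
  em <- as_pixel_matrix(em_image)
  tr <- as_similarity_transform(result)
  mats <- lapply(light_channels, as_pixel_matrix)
  d0 <- dim(mats[[1]])
  for (m in mats)
    if (!all(dim(m) == d0))
      stop("geometry error: light channels must share one shape",
           call. = FALSE)
  cc <- c((d0[2] - 1) / 2, (d0[1] - 1) / 2)  # rotate about channel centre
  out <- array(0, c(nrow(em), ncol(em), length(mats) + 1))
  for (i in seq_along(mats)) {
    out[, , i] <- .warp_similarity(mats[[i]], nrow(em), ncol(em),
                                   tr$scale, tr$rotation_deg,
                                   tr$t[1], tr$t[2], cc[1], cc[2],
                                   cc[1], cc[2],
                                   interpolation == "bilinear", 0)
  }
  out[, , length(mats) + 1] <- em
  dimnames(out) <- list(NULL, NULL,
                        c(paste0("light_", seq_along(mats)), "em"))
  out
}
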