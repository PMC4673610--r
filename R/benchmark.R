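# Synthetic random-dot benchmark: matrix generation, the image-degradation
# pipeline that emulates diffraction-limited re-imaging, and the
# alignment-efficiency / alignment-accuracy analyses.

PAPER_DOT_SET <- c(20, 50, 100, 200, 250, 500, 1000)

#' Specification of a synthetic random-dot matrix
#'
#' The in-silico stand-in for a stochastically micro-patterned coverslip: a
#' large binary matrix (default 10,000 x 10,000 px at the 65 nm/px sampling
#' of a 100x objective) with randomly placed, possibly overlapping dots.
#'
#' @param width,height matrix size in pixels.
#' @param dot_diameters_px vector of dot diameters in px, or `"random"`
#'   for the mixed set `c(20, 50, 100, 200, 250, 500, 1000)` with each
#'   diameter contributing an equal share of the dot area.
#' @param target_coverage foreground fraction to reach (measured by pixel
#'   count), within +/- 1% absolute; 0 gives a blank matrix.
#' @param seed RNG seed for dot placement.
#' @return a `DotMatrixSpec` list.
#' @export
dot_matrix_spec <- function(width = 10000, height = 10000,
                            dot_diameters_px = "random",
                            target_coverage = 0.10, seed = 0) {
  if (identical(dot_diameters_px, "random"))
    dot_diameters_px <- PAPER_DOT_SET
  if (!is.numeric(dot_diameters_px) || any(dot_diameters_px < 2))
    stop("dot diameters must be numeric and >= 2 px", call. = FALSE)
  if (target_coverage < 0 || target_coverage >= 1)
    stop("`target_coverage` must be in [0, 1)", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 dot_diameters_px = dot_diameters_px,
                 target_coverage = target_coverage, seed = seed),
            class = "DotMatrixSpec")
}

#' Generate a binary random-dot matrix
#'
#' Dots are placed at uniformly random centres (overlap permitted). A
#' mixed-diameter matrix emulates one generator run per dot size at a
#' common density: each diameter contributes an (approximately) equal
#' share of the total dot area, so small dots are numerous and large dots
#' rare — the size allocation is greedy on the accumulated nominal area
#' per diameter, largest first on ties. Dots are added until the measured
#' foreground fraction (direct pixel count) reaches the target coverage
#' within +/- 1% absolute.
#'
#' @param spec a [dot_matrix_spec()].
#' @return list with `image` (binary [raster_image()], values {0, 255},
#'   65 nm/px), `dots` (`data.frame`: x, y, diameter_px of every placed
#'   dot) and `coverage` (measured foreground fraction).
#' @export
generate_dot_matrix <- function(spec) {
  stopifnot(inherits(spec, "DotMatrixSpec"))
  w <- spec$width; h <- spec$height
  m <- matrix(0L, h, w)
  target <- spec$target_coverage
  if (target == 0)
    return(list(image = raster_image(m, pixel_size_nm = 65,
                                     modality = "binary"),
                dots = data.frame(x = numeric(0), y = numeric(0),
                                  diameter_px = numeric(0)),
                coverage = 0))
  dset <- sort(spec$dot_diameters_px, decreasing = TRUE)
  npx <- as.numeric(w) * h
  fg <- 0
  xs <- ys <- ds <- numeric(0)
  area_placed <- numeric(length(dset))  # nominal area budget per size
  dot_area <- pi * (dset / 2)^2
  with_seed(spec$seed, {
    placed <- 0L
    repeat {
      if (fg / npx >= target - 0.005) break
      if (placed >= 1e7)
        stop("coverage ", target, " not reached after 1e7 dot placements",
             call. = FALSE)
      # equal-area allocation: next dot comes from the size with the
      # smallest accumulated nominal area (dset sorted descending, so
      # ties go to the largest diameter)
      di <- which.min(area_placed)
      d <- dset[di]
      # a dot whose expected contribution would overshoot the coverage
      # band is replaced by the smallest diameter (only relevant when
      # large dots are a sizable fraction of a small matrix)
      if (dot_area[di] * (1 - fg / npx) / npx > target + 0.009 - fg / npx) {
        di <- length(dset); d <- dset[di]
      }
      area_placed[di] <- area_placed[di] + dot_area[di]
      cx <- runif(1, 0, w); cy <- runif(1, 0, h)
      r <- d / 2
      x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
      y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
      placed <- placed + 1L
      if (x1 >= x0 && y1 >= y0) {
        xw <- x0:x1; yw <- y0:y1
        cond <- outer((yw - cy)^2, (xw - cx)^2, "+") <= r^2
        if (any(cond)) {
          sub <- m[yw + 1, xw + 1, drop = FALSE]
          fg <- fg + sum(cond & sub == 0L)
          sub[cond] <- 255L
          m[yw + 1, xw + 1] <- sub
          xs <- c(xs, cx); ys <- c(ys, cy); ds <- c(ds, d)
        }
      }
    }
  })
  cov <- fg / npx
  if (abs(cov - target) > 0.01)
    stop("measured coverage ", signif(cov, 4),
         " outside +/-1% of target ", target, call. = FALSE)
  list(image = raster_image(m, pixel_size_nm = 65, modality = "binary"),
       dots = data.frame(x = xs, y = ys, diameter_px = ds),
       coverage = cov)
}

#' Crop overlapping tile pairs with known ground-truth shift
#'
#' @param matrix_img the source matrix ([raster_image()] or matrix).
#' @param n_pairs number of pairs.
#' @param overlap nominal overlap fraction (0.90 in the benchmark
#'   protocol); 1 gives identical tiles.
#' @param shift_mode `"axis"`: the full shift `round((1-overlap)*tile)`
#'   along one random axis; `"free"`: both components drawn per pair
#'   (uniform over `[-max_shift, max_shift]`), so no two pairs share a
#'   constant shift.
#' @param tile tile side length in px (default 2048, the camera raster).
#' @param seed RNG seed for crop positions and shifts.
#' @return list of pairs; each has `a`, `b` (matrices) and `true_shift`
#'   (`c(dx, dy)`: the crop-coordinate difference of `b` relative to `a`).
#' @export
crop_pairs <- function(matrix_img, n_pairs, overlap = 0.90,
                       shift_mode = c("free", "axis"), tile = 2048,
                       seed = 0) {
  shift_mode <- match.arg(shift_mode)
  m <- as_pixel_matrix(matrix_img)
  W <- ncol(m); H <- nrow(m)
  if (tile > W || tile > H)
    stop("tile size ", tile, " exceeds the matrix (", W, " x ", H, ")",
         call. = FALSE)
  if (overlap <= 0 || overlap > 1)
    stop("`overlap` must be in (0, 1]", call. = FALSE)
  max_s <- round((1 - overlap) * tile)
  pick1 <- function(v) v[sample.int(length(v), 1)]  # safe for length 1
  with_seed(seed, {
    lapply(seq_len(n_pairs), function(k) {
      if (max_s == 0) {
        sx <- 0L; sy <- 0L
      } else if (shift_mode == "axis") {
        s <- max_s * pick1(c(-1L, 1L))
        if (pick1(c(TRUE, FALSE))) { sx <- s; sy <- 0L }
        else { sx <- 0L; sy <- s }
      } else {
        sx <- pick1(seq(-max_s, max_s))
        sy <- pick1(seq(-max_s, max_s))
      }
      xa <- pick1(seq(max(0, -sx), W - tile - max(0, sx)))
      ya <- pick1(seq(max(0, -sy), H - tile - max(0, sy)))
      list(a = m[ya + (1:tile), xa + (1:tile)],
           b = m[ya + sy + (1:tile), xa + sx + (1:tile)],
           true_shift = c(sx, sy))
    })
  })
}

#' Image-degradation settings
#'
#' The pipeline that turns a crisp synthetic tile into something resembling
#' a diffraction-limited, noisy acquisition: area-average downscale by
#' `down_factor` (3.846 maps the 65 nm matrix pixels onto 250 nm optical
#' pixels), impulse ("single pixel") noise on a fraction of pixels (half
#' set to 0, half to 255), Gaussian blur, binarisation at
#' `binarize_threshold` (>= is foreground), and nearest-neighbour upscale
#' back to `restore_size`.
#'
#' @param down_factor downscale factor (>= 1).
#' @param noise_fraction fraction of pixels replaced by impulses, in
#'   [0, 0.5).
#' @param blur_sigma_px Gaussian sigma at the reduced scale, px.
#' @param binarize_threshold threshold on the 8-bit scale, in (0, 255).
#' @param restore_size output side length (scalar or `c(h, w)`); `NULL`
#'   restores the input size, `NA` skips restoration and returns the
#'   reduced-scale image.
#' @return a `DegradationConfig` list.
#' @export
degradation_config <- function(down_factor = 3.846, noise_fraction = 0.01,
                               blur_sigma_px = 1.0,
                               binarize_threshold = 100,
                               restore_size = NULL) {
  if (down_factor < 1) stop("`down_factor` must be >= 1", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction >= 0.5)
    stop("`noise_fraction` must be in [0, 0.5)", call. = FALSE)
  if (binarize_threshold <= 0 || binarize_threshold >= 255)
    stop("`binarize_threshold` must be in (0, 255)", call. = FALSE)
  structure(list(down_factor = down_factor,
                 noise_fraction = noise_fraction,
                 blur_sigma_px = blur_sigma_px,
                 binarize_threshold = binarize_threshold,
                 restore_size = restore_size),
            class = "DegradationConfig")
}

#' Degrade an image through the synthetic re-imaging pipeline
#'
#' @param image 8-bit-scale image (matrix or [raster_image()]).
#' @param config a [degradation_config()].
#' @param seed RNG seed for the impulse noise.
#' @return strictly binary matrix (values 0/255) of the restored size.
#' @export
degrade <- function(image, config = degradation_config(), seed = 0) {
  stopifnot(inherits(config, "DegradationConfig"))
  m <- as_pixel_matrix(image)
  if (max(m) > 255 + 1e-6 || min(m) < -1e-6)
    stop("degrade() expects 8-bit-scale input (0..255)", call. = FALSE)
  m <- pmin(pmax(m, 0), 255)
  h <- nrow(m); w <- ncol(m)
  rs <- config$restore_size
  if (is.null(rs)) rs <- c(h, w)       # NA skips restoration entirely
  if (length(rs) == 1) rs <- c(rs, rs)
  df <- config$down_factor
  small <- if (df > 1) .resize_area(m, floor(h / df), floor(w / df)) else m
  if (config$noise_fraction > 0) {
    n <- round(config$noise_fraction * length(small))
    if (n > 0) {
      idx <- with_seed(seed, sample.int(length(small), n))
      small[idx] <- rep(c(0, 255), length.out = n)
    }
  }
  if (config$blur_sigma_px > 0)
    small <- .gauss_blur(small, config$blur_sigma_px)
  small <- ifelse(small >= config$binarize_threshold, 255, 0)
  rdim <- dim(small)
  if (!anyNA(rs) && !all(dim(small) == rs))
    small <- .resize_nearest(small, rs[1], rs[2])
  attr(small, "reduced_dim") <- as.integer(rdim)
  small
}

# Degrade-and-register one tile pair, magnification-rescaled to side
# length `m_side`. Registration and error bookkeeping happen at the
# information-limited sampling: the reduced grid the degradation pipeline
# binarises on (the restored image is a nearest-neighbour upsampling of
# it, so it carries no extra information, and the published error is
# printed in these diffraction-limited pixels). Without degradation the
# evaluation frame is `m_side` itself.
register_pair <- function(pair, m_side, config, seed, tile) {
  prep <- function(x) {
    y <- if (m_side != tile) .resize_area(x, m_side, m_side) else x
    if (is.null(config)) y else {
      cfg <- config; cfg$restore_size <- NA  # stay at the reduced scale
      degrade(y, cfg, seed = seed)
    }
  }
  a <- prep(pair$a)
  seed <- seed + 1
  b <- prep(pair$b)
  eval_side <- nrow(a)
  truth <- pair$true_shift * (m_side / tile) * (eval_side / m_side)
  est <- tryCatch(phase_correlate(a, b), error = function(e) NULL)
  if (is.null(est))
    return(list(ok = FALSE, truth = truth, est = c(NA, NA),
                err = c(NA, NA), dev = Inf))
  err <- c(est$dx, est$dy) - truth
  list(ok = TRUE, truth = truth, est = c(est$dx, est$dy), err = err,
       dev = sqrt(sum(err^2)))
}

#' Alignment efficiency across dot sizes and magnifications
#'
#' For every (dot spec x magnification) cell: generate the matrix, crop
#' tile pairs at the protocol overlap, rescale to the magnification's
#' sampling, degrade both tiles, register by translation-only phase
#' correlation, and score success as total deviation <= `success_tol_px`.
#' Deviations are measured in pixels of the information-limited
#' (degraded) sampling — the restored image is a nearest-neighbour
#' upsampling of it and carries no extra information. Failed
#' registrations count as failures, not errors.
#'
#' @param dot_specs list of [dot_matrix_spec()]s, or a vector mixing
#'   diameters and the token `"random"` (specs are then built with
#'   `matrix_size` and `coverage`).
#' @param magnifications objective magnifications (subset of the
#'   [magnification_table()] names).
#' @param n_pairs tile pairs per cell.
#' @param overlap pair overlap fraction.
#' @param success_tol_px success tolerance in px.
#' @param config a [degradation_config()].
#' @param seed global seed; expanded deterministically per stage.
#' @param tile tile side, px.
#' @param matrix_size,coverage used when `dot_specs` is a plain vector.
#' @param shift_mode passed to [crop_pairs()].
#' @param quiet suppress progress logging.
#' @return `data.frame` (class `EfficiencyReport`): dots, magnification,
#'   n_pairs, n_success, efficiency.
#' @export
run_efficiency <- function(dot_specs = c(PAPER_DOT_SET, "random"),
                           magnifications = c(100, 60, 40, 20, 10, 4),
                           n_pairs = 16, overlap = 0.90,
                           success_tol_px = 3,
                           config = degradation_config(), seed = 0,
                           tile = 2048, matrix_size = 10000,
                           coverage = 0.10, shift_mode = "axis",
                           quiet = FALSE) {
  if (!is.list(dot_specs)) {
    labels <- as.character(dot_specs)
    dot_specs <- lapply(seq_along(labels), function(i) {
      dd <- if (labels[i] == "random") "random" else as.numeric(labels[i])
      dot_matrix_spec(matrix_size, matrix_size, dd, coverage,
                      seed = split_seed(seed, i))
    })
  } else {
    labels <- vapply(dot_specs, function(s)
      if (length(s$dot_diameters_px) > 1) "random" else
        as.character(s$dot_diameters_px), character(1))
  }
  factors <- magnification_scale_factors(magnifications)
  out <- list()
  for (i in seq_along(dot_specs)) {
    log_stage("efficiency: matrix '", labels[i], "'", quiet = quiet)
    gen <- generate_dot_matrix(dot_specs[[i]])
    pairs <- crop_pairs(gen$image, n_pairs, overlap = overlap,
                        shift_mode = shift_mode, tile = tile,
                        seed = split_seed(seed, 1000 + i))
    rm(gen); gc(FALSE)
    for (j in seq_along(factors)) {
      f <- factors[j]
      m_side <- max(16L, round(tile / f))
      devs <- vapply(seq_along(pairs), function(k) {
        register_pair(pairs[[k]], m_side, config,
                      seed = split_seed(seed, 1e5 + i * 1000 + j * 50 + k),
                      tile = tile)$dev
      }, numeric(1))
      ok <- sum(devs <= success_tol_px)
      out[[length(out) + 1]] <-
        data.frame(dots = labels[i], magnification = magnifications[j],
                   n_pairs = length(pairs), n_success = ok,
                   efficiency = ok / length(pairs))
    }
    rm(pairs); gc(FALSE)
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("EfficiencyReport", "data.frame")
  rep
}

#' Alignment accuracy under per-pair shifts and random rescaling
#'
#' The accuracy protocol: from the mixed-dot-size matrix, crop
#' `n_base_pairs` tile pairs with per-pair varied shifts; draw
#' `n_scale_factors` random scale factors from `scale_range`; for every
#' (pair x factor) combination rescale both tiles to
#' `round(tile / factor)` px, run the degradation pipeline, and register
#' by integer-pixel phase correlation at the information-limited
#' (degraded) sampling; the true shift becomes continuous-valued there,
#' so integer registration has an irreducible rounding error of
#' `E sqrt(U^2+V^2) = 0.3826` px. The per-pair error components against
#' the rescaled ground truth give the total deviation
#' `sqrt(x^2 + y^2)`, in pixels of that sampling (250 nm at factor 1 —
#' the scale the published accuracy is quoted on); the report carries
#' per-pair deviations, their mean and the standard error of the mean.
#' Failed registrations (deviation above `success_tol_px`) are excluded
#' from the mean and reported separately.
#'
#' @param spec a mixed-size [dot_matrix_spec()]; `NULL` builds the default
#'   from `seed`.
#' @param n_base_pairs base tile pairs (16 in the protocol).
#' @param n_scale_factors scale factors (7, so 16 x 7 = 112 records).
#' @param scale_range range the factors are drawn from, default (1, 4).
#' @param config a [degradation_config()], or `NULL` to disable
#'   degradation (used for the rounding-floor oracle).
#' @param success_tol_px deviation above this marks a failed alignment.
#' @param seed global seed; expanded per stage.
#' @param tile tile side, px.
#' @param quiet suppress progress logging.
#' @return an `AccuracyReport`: list with `records` (`data.frame`:
#'   pair_id, scale_factor, true_dx, true_dy, est_dx, est_dy, err_x,
#'   err_y, total_deviation, success), `mean_deviation`, `sem`,
#'   `n_failed`, `n_records`.
#' @export
run_accuracy <- function(spec = NULL, n_base_pairs = 16,
                         n_scale_factors = 7, scale_range = c(1, 4),
                         config = degradation_config(),
                         success_tol_px = 3, seed = 0, tile = 2048,
                         quiet = FALSE) {
  if (is.null(spec))
    spec <- dot_matrix_spec(seed = split_seed(seed, 1))
  log_stage("accuracy: generating ", spec$width, " x ", spec$height,
            " mixed-dot matrix", quiet = quiet)
  gen <- generate_dot_matrix(spec)
  pairs <- crop_pairs(gen$image, n_base_pairs, overlap = 0.90,
                      shift_mode = "free", tile = tile,
                      seed = split_seed(seed, 2))
  rm(gen); gc(FALSE)
  factors <- with_seed(split_seed(seed, 3),
                       runif(n_scale_factors, scale_range[1],
                             scale_range[2]))
  rows <- list()
  for (j in seq_along(factors)) {
    s <- factors[j]
    m_side <- round(tile / s)
    log_stage(sprintf("accuracy: scale factor %.3f (%d px frame)", s,
                      m_side), quiet = quiet)
    for (k in seq_along(pairs)) {
      r <- register_pair(pairs[[k]], m_side, config,
                         seed = split_seed(seed, 1e6 + j * 100 + k),
                         tile = tile)
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = k, scale_factor = s,
        true_dx = r$truth[1], true_dy = r$truth[2],
        est_dx = r$est[1], est_dy = r$est[2],
        err_x = r$err[1], err_y = r$err[2],
        total_deviation = r$dev,
        success = is.finite(r$dev) && r$dev <= success_tol_px)
    }
  }
  records <- do.call(rbind, rows)
  devs <- records$total_deviation[records$success]
  structure(list(records = records,
                 mean_deviation = mean(devs),
                 sem = sd(devs) / sqrt(length(devs)),
                 n_failed = sum(!records$success),
                 n_records = nrow(records)),
            class = "AccuracyReport")
}

#' @export
print.AccuracyReport <- function(x, ...) {
  cat(sprintf(
    "<AccuracyReport> %d pairs: mean deviation %.3f px (SEM %.3f), %d failed\n",
    x$n_records, x$mean_deviation, x$sem, x$n_failed))
  invisible(x)
}

#' Randomly delete whole islands from a pattern
#'
#' Emulates gold lift-off during sample handling: `round(fraction * N)`
#' islands are removed uniformly at random.
#'
#' @param mask a pattern mask with >= 1 island.
#' @param fraction fraction of islands to delete, in [0, 1).
#' @param seed RNG seed.
#' @return list with `mask` (the thinned `PatternMask`) and
#'   `deleted_labels`.
#' @export
simulate_island_loss <- function(mask, fraction, seed = 0) {
  if (fraction < 0 || fraction >= 1)
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  m <- as_mask_matrix(mask)
  tab <- label_islands(m, min_area_px = 1)
  if (nrow(tab) == 0) stop("mask has no islands", call. = FALSE)
  k <- round(fraction * nrow(tab))
  if (k == 0)
    return(list(mask = pattern_mask(m), deleted_labels = integer(0)))
  del <- with_seed(seed, sample(tab$label, k))
  lm <- attr(tab, "label_map")
  m[lm %in% del] <- FALSE
  list(mask = pattern_mask(m), deleted_labels = sort(del))
}
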