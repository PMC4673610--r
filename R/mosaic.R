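#' Integer-pixel translation registration by spectral correlation
#'
#' Estimates the translation between two same-shape images from the peak of
#' the normalised cross-power spectrum (phase correlation). The returned
#' shift `(dx, dy)` is the displacement that content of `a` has in `b`:
#' `a(x, y) ~ b(x - dx, y - dy)`. Integer-pixel estimation is the default;
#' parabolic sub-pixel refinement is available behind `subpixel = TRUE`.
#'
#' Images are mean-subtracted and edge-tapered (raised cosine over
#' `taper` of each edge) to suppress wrap-around artifacts, then padded to
#' the next 2/3/5-smooth size for the FFT. Ties at the correlation peak are
#' broken by the smallest shift norm, then smallest `dy`, then `dx`.
#'
#' @param a,b images (matrix, [raster_image()] or `PatternMask`), same
#'   shape, non-constant.
#' @param taper fraction of each edge tapered before the transform.
#' @param subpixel add parabolic sub-pixel refinement fields `dx_sub`,
#'   `dy_sub` (default off: the alignment accuracy of the whole pipeline is
#'   characterised for the integer-grid estimator).
#' @return a `ShiftEstimate`: list with integer `dx`, `dy`, `score`
#'   (normalised correlation peak in [0, 1]) and, with `subpixel = TRUE`,
#'   `dx_sub`/`dy_sub` offsets.
#' @export
phase_correlate <- function(a, b, taper = 0.1, subpixel = FALSE) {
  A <- as_pixel_matrix(a); B <- as_pixel_matrix(b)
  if (!all(dim(A) == dim(B)))
    stop("images must have the same shape", call. = FALSE)
  if (sd(A) == 0 || sd(B) == 0)
    stop("degenerate input: constant image has no correlation peak",
         call. = FALSE)
  w <- taper_window(nrow(A), ncol(A), taper)
  pc_matrices((A - mean(A)) * w, (B - mean(B)) * w, subpixel = subpixel)
}

# Phase correlation on prepared (windowed, zero-mean) matrices.
pc_matrices <- function(am, bm, subpixel = FALSE) {
  nr <- nrow(am); nc <- ncol(am)
  pr <- next_fast_size(nr); pcn <- next_fast_size(nc)
  za <- matrix(0, pr, pcn); za[1:nr, 1:nc] <- am
  zb <- matrix(0, pr, pcn); zb[1:nr, 1:nc] <- bm
  # one complex FFT carries both real transforms (Hermitian split)
  Z <- fft(za + (0+1i) * zb)
  Zr <- Conj(Z[c(1, pr:2), c(1, pcn:2), drop = FALSE])
  Fa <- (Z + Zr) / 2
  Fb <- (Z - Zr) / (0+2i)
  pc_peak(Fa, Fb, pr, pcn, subpixel = subpixel)
}

# FFT of a single prepared image padded to (pr, pcn); used where one side
# of the correlation is fixed across many calls.
pc_fft <- function(m, pr, pcn) {
  z <- matrix(0, pr, pcn)
  z[1:nrow(m), 1:ncol(m)] <- m
  fft(z)
}

pc_peak <- function(Fa, Fb, pr, pcn, subpixel = FALSE) {
  P <- Fa * Conj(Fb)
  Rn <- P / pmax(Mod(P), 1e-12)
  r <- Re(fft(Rn, inverse = TRUE)) / (pr * pcn)
  peak <- max(r)
  cand <- which(r >= peak - 1e-9, arr.ind = TRUE)
  dys <- cand[, 1] - 1; dxs <- cand[, 2] - 1
  dys <- ifelse(dys > pr / 2, dys - pr, dys)
  dxs <- ifelse(dxs > pcn / 2, dxs - pcn, dxs)
  ord <- order(dxs^2 + dys^2, dys, dxs)
  dy <- dys[ord[1]]; dx <- dxs[ord[1]]
  out <- list(dx = as.integer(dx), dy = as.integer(dy),
              score = max(0, min(1, peak)))
  if (subpixel) {
    ci <- ((dx %% pcn)) + 1; ri <- ((dy %% pr)) + 1
    nxt <- function(i, n) (i %% n) + 1
    prv <- function(i, n) ((i - 2) %% n) + 1
    para <- function(m1, m0, p1) {
      d <- m1 - 2 * m0 + p1
      if (d >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / d))
    }
    out$dx_sub <- para(r[ri, prv(ci, pcn)], r[ri, ci], r[ri, nxt(ci, pcn)])
    out$dy_sub <- para(r[prv(ri, pr), ci], r[ri, ci], r[nxt(ri, pr), ci])
  }
  class(out) <- "ShiftEstimate"
  out
}

#' @export
print.ShiftEstimate <- function(x, ...) {
  cat(sprintf("<ShiftEstimate> (dx, dy) = (%d, %d), score %.4f\n",
              x$dx, x$dy, x$score))
  invisible(x)
}

#' Bundle tiles with their nominal grid layout
#'
#' @param tiles list of same-shape images in the order given by `order`.
#' @param nrow,ncol grid dimensions.
#' @param overlap nominal overlap fraction between neighbouring tiles
#'   (default 0.30, the value that works best for bright-field coverslip
#'   maps).
#' @param order `"row-major"` or `"col-major"` enumeration of `tiles`.
#' @param nominal_offsets optional n x 2 matrix of nominal (x, y) pixel
#'   offsets overriding the regular grid (e.g. stage positions).
#' @return a `TileSet`.
#' @export
tile_set <- function(tiles, nrow, ncol, overlap = 0.30,
                     order = c("row-major", "col-major"),
                     nominal_offsets = NULL) {
  order <- match.arg(order)
  if (length(tiles) != nrow * ncol)
    stop("need ", nrow * ncol, " tiles for a ", nrow, "x", ncol, " grid",
         call. = FALSE)
  if (overlap <= 0 || overlap >= 1)
    stop("`overlap` must be in (0, 1)", call. = FALSE)
  mats <- lapply(tiles, as_pixel_matrix)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), logical(1))))
    stop("all tiles must have the same shape", call. = FALSE)
  grid <- if (order == "row-major")
    data.frame(row = rep(seq_len(nrow), each = ncol),
               col = rep(seq_len(ncol), times = nrow))
  else
    data.frame(row = rep(seq_len(nrow), times = ncol),
               col = rep(seq_len(ncol), each = nrow))
  if (is.null(nominal_offsets)) {
    step_x <- round(d[2] * (1 - overlap))
    step_y <- round(d[1] * (1 - overlap))
    nominal_offsets <- cbind((grid$col - 1) * step_x,
                             (grid$row - 1) * step_y)
  }
  structure(list(tiles = mats, grid = grid, overlap = overlap,
                 nominal = nominal_offsets, tile_dim = d),
            class = "TileSet")
}

#' Stitch a tile grid into a global map
#'
#' Estimates pairwise shifts between grid neighbours on their nominal
#' overlap strips (searched over the nominal overlap +/- 25%), then picks a
#' consistent global placement along a maximum-score spanning set of links
#' anchored at the top-left tile. Overlapping pixels are resolved
#' last-writer-wins in grid order, so the result is invariant to the
#' enumeration order of the tiles.
#'
#' @param tiles a [tile_set()].
#' @param overlap_fraction nominal overlap fraction (default from the tile
#'   set).
#' @param score_floor links scoring below this fall back to their nominal
#'   placement with a warning.
#' @return a `GlobalMap`: list with `image` ([raster_image()]), `offsets`
#'   (`data.frame`: tile_id, nominal_x, nominal_y, resolved_x, resolved_y,
#'   score) and the tile dimensions.
#' @export
stitch_grid <- function(tiles, overlap_fraction = NULL, score_floor = 0.05) {
  ts <- tiles
  if (!inherits(ts, "TileSet")) stop("`tiles` must be a tile_set()",
                                     call. = FALSE)
  ov <- if (is.null(overlap_fraction)) ts$overlap else overlap_fraction
  n <- length(ts$tiles)
  h <- ts$tile_dim[1]; w <- ts$tile_dim[2]
  key <- order(ts$grid$row, ts$grid$col)   # canonical grid order
  pos <- matrix(NA_real_, n, 2)
  if (n == 1) {
    pos[1, ] <- c(0, 0)
    scores <- NA_real_
  } else {
    wo <- max(2L, round(w * ov)); ho <- max(2L, round(h * ov))
    mx <- max(1L, round(0.25 * wo)); my <- max(1L, round(0.25 * ho))
    edges <- list()
    idx_of <- function(r, c) which(ts$grid$row == r & ts$grid$col == c)
    for (i in key) {
      r <- ts$grid$row[i]; c <- ts$grid$col[i]
      jr <- idx_of(r, c + 1)
      if (length(jr) == 1) {
        x0 <- w - wo - mx
        A <- ts$tiles[[i]][, (x0 + 1):w, drop = FALSE]
        B <- ts$tiles[[jr]][, 1:(wo + mx), drop = FALSE]
        est <- tryCatch(phase_correlate(A, B),
                        error = function(e) list(dx = 0L, dy = 0L, score = 0))
        edges[[length(edges) + 1]] <-
          list(i = i, j = jr, rel = c(x0 + est$dx, est$dy),
               nominal_rel = ts$nominal[jr, ] - ts$nominal[i, ],
               score = est$score)
      }
      jd <- idx_of(r + 1, c)
      if (length(jd) == 1) {
        y0 <- h - ho - my
        A <- ts$tiles[[i]][(y0 + 1):h, , drop = FALSE]
        B <- ts$tiles[[jd]][1:(ho + my), , drop = FALSE]
        est <- tryCatch(phase_correlate(A, B),
                        error = function(e) list(dx = 0L, dy = 0L, score = 0))
        edges[[length(edges) + 1]] <-
          list(i = i, j = jd, rel = c(est$dx, y0 + est$dy),
               nominal_rel = ts$nominal[jd, ] - ts$nominal[i, ],
               score = est$score)
      }
    }
    # reject links that are weak or wildly off-nominal
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      off <- abs(e$rel - e$nominal_rel)
      if (e$score < score_floor || off[1] >= wo || off[2] >= ho) {
        warning("tile link ", e$i, " -> ", e$j,
                " below score floor or off-nominal; using nominal placement",
                call. = FALSE)
        edges[[k]]$rel <- e$nominal_rel
        edges[[k]]$score <- 0
      }
    }
    # maximum-score spanning set (Prim), anchored at grid (1,1)
    anchor <- key[1]
    pos[anchor, ] <- c(0, 0)
    placed <- rep(FALSE, n); placed[anchor] <- TRUE
    scores <- rep(NA_real_, n)
    for (step in seq_len(n - 1)) {
      best <- NULL; best_score <- -Inf
      for (e in edges) {
        if (placed[e$i] && !placed[e$j]) {
          cand <- list(from = e$i, to = e$j, rel = e$rel, score = e$score)
        } else if (placed[e$j] && !placed[e$i]) {
          cand <- list(from = e$j, to = e$i, rel = -e$rel, score = e$score)
        } else next
        if (cand$score > best_score + 1e-12) {
          best <- cand; best_score <- cand$score
        }
      }
      if (is.null(best)) {  # disconnected: fall back to nominal
        togo <- which(!placed)[1]
        pos[togo, ] <- ts$nominal[togo, ] - ts$nominal[anchor, ]
        placed[togo] <- TRUE
        next
      }
      pos[best$to, ] <- pos[best$from, ] + best$rel
      scores[best$to] <- best$score
      placed[best$to] <- TRUE
    }
  }
  pos[, 1] <- pos[, 1] - min(pos[, 1])
  pos[, 2] <- pos[, 2] - min(pos[, 2])
  canvas <- matrix(0, max(pos[, 2]) + h, max(pos[, 1]) + w)
  for (i in key)  # last-writer-wins in canonical grid order
    canvas[pos[i, 2] + (1:h), pos[i, 1] + (1:w)] <- ts$tiles[[i]]
  offsets <- data.frame(tile_id = seq_len(n),
                        nominal_x = ts$nominal[, 1],
                        nominal_y = ts$nominal[, 2],
                        resolved_x = pos[, 1], resolved_y = pos[, 2],
                        score = if (n == 1) NA_real_ else scores)
  structure(list(image = raster_image(canvas), offsets = offsets,
                 tile_dim = ts$tile_dim, overlap = ov),
            class = "GlobalMap")
}

#' @export
print.GlobalMap <- function(x, ...) {
  cat(sprintf("<GlobalMap> %d x %d px from %d tiles\n",
              ncol(x$image$pixels), nrow(x$image$pixels), nrow(x$offsets)))
  invisible(x)
}

#' Embed a high-resolution tile into a lower-resolution base image
#'
#' Downscales the tile to the base sampling, finds its translation in the
#' base by phase correlation, and composites an "enhanced" image in which
#' the placed region carries the high-resolution content. Rotation is fixed
#' at zero (same mounting for both acquisitions).
#'
#' @param base low-resolution image whose field of view contains the tile.
#' @param tile high-resolution image.
#' @param scale_ratio base pixel size / tile pixel size, or `"auto"` to use
#'   the images' `pixel_size_nm` metadata.
#' @param score_floor minimum correlation peak; below it a
#'   placement-not-found error is raised.
#' @param output `"base"`: composite at base resolution; `"tile"`:
#'   composite on a canvas upsampled to the tile resolution.
#' @return list with `transform` (a [similarity_transform()] mapping tile
#'   pixel coordinates into base pixel coordinates, rotation 0), `placement`
#'   (x, y of the tile's top-left corner in base pixels), `score`, and
#'   `composite` (a [raster_image()]).
#' @export
embed_highres <- function(base, tile, scale_ratio = "auto",
                          score_floor = 0.05,
                          output = c("base", "tile")) {
  output <- match.arg(output)
  B <- as_pixel_matrix(base); Tm <- as_pixel_matrix(tile)
  if (identical(scale_ratio, "auto")) {
    bp <- if (inherits(base, "RasterImage")) base$pixel_size_nm else NULL
    tp <- if (inherits(tile, "RasterImage")) tile$pixel_size_nm else NULL
    if (is.null(bp) || is.null(tp))
      stop("scale_ratio = \"auto\" needs pixel_size_nm on both images",
           call. = FALSE)
    scale_ratio <- bp / tp
  }
  if (!is.numeric(scale_ratio) || scale_ratio <= 0)
    stop("`scale_ratio` must be positive", call. = FALSE)
  small <- if (abs(scale_ratio - 1) < 1e-12) Tm else
    .resize_area(Tm, max(1L, round(nrow(Tm) / scale_ratio)),
                 max(1L, round(ncol(Tm) / scale_ratio)))
  hs <- nrow(small); ws <- ncol(small)
  if (hs > nrow(B) || ws > ncol(B))
    stop("tile field of view exceeds the base image", call. = FALSE)
  # centre the (tapered) template on a zero canvas so the global edge taper
  # cannot eat it, correlate, then undo the centring offset
  c0 <- c(floor((ncol(B) - ws) / 2), floor((nrow(B) - hs) / 2))
  canvas <- matrix(0, nrow(B), ncol(B))
  tw <- taper_window(hs, ws, 0.1)
  canvas[c0[2] + (1:hs), c0[1] + (1:ws)] <- (small - mean(small)) * tw
  wb <- taper_window(nrow(B), ncol(B), 0.1)
  est <- pc_matrices((B - mean(B)) * wb, canvas)
  if (est$score < score_floor)
    stop("placement not found: correlation peak ", signif(est$score, 3),
         " below floor ", score_floor, call. = FALSE)
  place <- c(est$dx + c0[1], est$dy + c0[2])
  if (output == "base") {
    comp <- B
    ys <- place[2] + (1:hs); xs <- place[1] + (1:ws)
    ok_y <- ys >= 1 & ys <= nrow(B); ok_x <- xs >= 1 & xs <= ncol(B)
    comp[ys[ok_y], xs[ok_x]] <- small[ok_y, ok_x]
    comp_img <- raster_image(comp,
      pixel_size_nm = if (inherits(base, "RasterImage"))
        base$pixel_size_nm else NULL, modality = "sem")
  } else {
    up <- .resize_bilinear(B, round(nrow(B) * scale_ratio),
                           round(ncol(B) * scale_ratio))
    ph <- round(place[2] * scale_ratio); pw <- round(place[1] * scale_ratio)
    ys <- ph + (1:nrow(Tm)); xs <- pw + (1:ncol(Tm))
    ok_y <- ys >= 1 & ys <= nrow(up); ok_x <- xs >= 1 & xs <= ncol(up)
    up[ys[ok_y], xs[ok_x]] <- Tm[ok_y, ok_x]
    comp_img <- raster_image(up,
      pixel_size_nm = if (inherits(tile, "RasterImage"))
        tile$pixel_size_nm else NULL, modality = "sem")
  }
  tr <- similarity_transform(scale = 1 / scale_ratio, rotation_deg = 0,
                             t = place)
  tr$score <- est$score
  list(transform = tr, placement = place, score = est$score,
       composite = comp_img)
}
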