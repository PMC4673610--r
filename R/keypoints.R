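# Scale- and rotation-invariant keypoints on micro-pattern images.
# Detector: scale-normalised determinant-of-Hessian blob response over a
# Gaussian octave pyramid (the contract the popular SURF plugin fulfils,
# reimplemented from scratch). Descriptor: oriented 4x4-cell gradient
# summary (sum dx, sum |dx|, sum dy, sum |dy| per cell), L2-normalised.

# determinant of Hessian, scale-normalised by sigma^4
doh_response <- function(L, sigma) {
  nr <- nrow(L); nc <- ncol(L)
  xr <- c(2:nc, nc); xl <- c(1, 1:(nc - 1))
  yd <- c(2:nr, nr); yu <- c(1, 1:(nr - 1))
  Lxx <- L[, xr, drop = FALSE] - 2 * L + L[, xl, drop = FALSE]
  Lyy <- L[yd, , drop = FALSE] - 2 * L + L[yu, , drop = FALSE]
  Lxy <- (L[yd, xr, drop = FALSE] + L[yu, xl, drop = FALSE] -
            L[yd, xl, drop = FALSE] - L[yu, xr, drop = FALSE]) / 4
  sigma^4 * (Lxx * Lyy - Lxy^2)
}

# max over the 3x3 neighbourhood (replicated borders)
nb_max <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- c(2:nc, nc); xl <- c(1, 1:(nc - 1))
  yd <- c(2:nr, nr); yu <- c(1, 1:(nr - 1))
  out <- pmax(m, m[, xr], m[, xl], m[yd, ], m[yu, ],
              m[yd, xr], m[yd, xl], m[yu, xr], m[yu, xl])
  matrix(out, nr, nc)
}

bilinear_sample <- function(M, x, y) {
  nr <- nrow(M); nc <- ncol(M)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  inb <- x >= -0.5 & x <= nc - 0.5 & y >= -0.5 & y <= nr - 0.5
  xa <- cl(x0, 0, nc - 1); xb <- cl(x0 + 1, 0, nc - 1)
  ya <- cl(y0, 0, nr - 1); yb <- cl(y0 + 1, 0, nr - 1)
  v <- (1 - fy) * ((1 - fx) * M[cbind(ya + 1, xa + 1)] +
                   fx * M[cbind(ya + 1, xb + 1)]) +
    fy * ((1 - fx) * M[cbind(yb + 1, xa + 1)] +
          fx * M[cbind(yb + 1, xb + 1)])
  v[!inb] <- 0
  v
}

kp_orientation <- function(gx, gy, x, y, sigma) {
  r <- ceiling(4.5 * sigma)
  xs <- seq(max(0, round(x) - r), min(ncol(gx) - 1, round(x) + r))
  ys <- seq(max(0, round(y) - r), min(nrow(gx) - 1, round(y) + r))
  X <- rep(xs, each = length(ys)); Y <- rep(ys, times = length(xs))
  d2 <- (X - x)^2 + (Y - y)^2
  keep <- d2 <= r^2
  X <- X[keep]; Y <- Y[keep]; d2 <- d2[keep]
  ix <- cbind(Y + 1, X + 1)
  vx <- gx[ix]; vy <- gy[ix]
  mag <- sqrt(vx^2 + vy^2)
  w <- mag * exp(-d2 / (2 * (2.5 * sigma)^2))
  ang <- atan2(-vy, vx)  # CCW-positive in the displayed image (y down)
  bin <- (floor((ang + pi) / (2 * pi) * 36) %% 36) + 1
  h <- numeric(36)
  acc <- tapply(w, bin, sum)
  h[as.integer(names(acc))] <- acc
  # circular smoothing, twice
  k <- c(1, 4, 6, 4, 1) / 16
  for (i in 1:2) {
    hp <- c(h[35:36], h, h[1:2])
    h <- vapply(1:36, function(j) sum(hp[j:(j + 4)] * k), numeric(1))
  }
  j <- which.max(h)
  jl <- if (j == 1) 36 else j - 1
  jr <- if (j == 36) 1 else j + 1
  den <- h[jl] - 2 * h[j] + h[jr]
  off <- if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (h[jl] - h[jr]) / den))
  ang_deg <- ((j - 0.5 + off) * 10) - 180
  ang_deg
}

kp_descriptor <- function(gx, gy, x, y, sigma, ori_deg) {
  grid <- seq(-9.5, 9.5, by = 1)  # 20 x 20 samples at sigma spacing
  U <- rep(grid, each = 20); V <- rep(grid, times = 20)
  th <- ori_deg * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  # descriptor frame -> image offsets (display rotation)
  px <- x + sigma * (c0 * U + s0 * V)
  py <- y + sigma * (-s0 * U + c0 * V)
  gxs <- bilinear_sample(gx, px, py)
  gys <- bilinear_sample(gy, px, py)
  gu <- c0 * gxs - s0 * gys
  gv <- s0 * gxs + c0 * gys
  w <- exp(-(U^2 + V^2) / (2 * 10^2))
  cell <- (pmin(floor((U + 10) / 5), 3)) * 4 + pmin(floor((V + 10) / 5), 3)
  d <- numeric(64)
  for (cc in 0:15) {
    s <- cell == cc
    d[cc * 4 + 1] <- sum(w[s] * gu[s])
    d[cc * 4 + 2] <- sum(w[s] * abs(gu[s]))
    d[cc * 4 + 3] <- sum(w[s] * gv[s])
    d[cc * 4 + 4] <- sum(w[s] * abs(gv[s]))
  }
  n <- sqrt(sum(d^2))
  if (n < 1e-12) return(NULL)
  d / n
}

empty_keypoints <- function() {
  structure(list(table = data.frame(x = numeric(0), y = numeric(0),
                                    scale = numeric(0),
                                    orientation = numeric(0),
                                    response = numeric(0)),
                 desc = matrix(numeric(0), 0, 64)),
            class = "Keypoints")
}

#' Detect scale-invariant blob keypoints
#'
#' Multi-scale blob detection: scale-normalised determinant-of-Hessian
#' responses over a Gaussian octave pyramid (>= 4 octave-spaced scales),
#' 26-neighbourhood local maxima above a response threshold, sub-pixel
#' position refinement, dominant-gradient orientation, and a 4x4-cell
#' oriented gradient descriptor (64-dimensional, unit norm). Intended to be
#' run on binary pattern masks so that bright-field and back-scatter
#' modalities, which have opposite contrast, become directly comparable.
#'
#' @param image matrix, [raster_image()] or `PatternMask`; constant images
#'   yield an empty keypoint set.
#' @param scales_per_octave intermediate scales per octave.
#' @param base_sigma detection scale of the finest level, px.
#' @param response_threshold determinant-of-Hessian threshold on the
#'   unit-normalised image.
#' @param n_octaves number of octaves, `NULL` = derived from image size.
#' @param max_keypoints keep at most this many, strongest first.
#' @return a `Keypoints` object: `table` (`data.frame`: x, y, scale,
#'   orientation, response; coordinates 0-based) and `desc` (n x 64 matrix,
#'   rows unit-norm).
#' @export
detect_keypoints <- function(image, scales_per_octave = 3, base_sigma = 1.6,
                             response_threshold = 2e-4, n_octaves = NULL,
                             max_keypoints = 2000) {
  px <- if (inherits(image, "PatternMask")) image$mask + 0 else
    as_pixel_matrix(image)
  rng <- range(px)
  if (diff(rng) == 0) return(empty_keypoints())
  I <- (px - rng[1]) / diff(rng)
  if (is.null(n_octaves))
    n_octaves <- max(1L, min(7L, floor(log2(min(dim(I)) / 12)) + 1L))
  S <- scales_per_octave
  sig <- base_sigma * 2^((0:(S + 1)) / S)
  rows <- list(); descs <- list()
  Io <- I
  for (o in 0:(n_octaves - 1)) {
    if (min(dim(Io)) < 12) break
    L <- lapply(sig, function(s) .gauss_blur(Io, s))
    D <- mapply(doh_response, L, sig, SIMPLIFY = FALSE)
    for (k in 2:(S + 1)) {
      m <- D[[k]]
      nbm <- nb_max(m)
      cond <- m >= nbm & m >= nb_max(D[[k - 1]]) & m >= nb_max(D[[k + 1]]) &
        m > response_threshold
      # keep clear of the border where derivatives are one-sided
      b <- 3L
      cond[c(seq_len(b), nrow(m) - seq_len(b) + 1), ] <- FALSE
      cond[, c(seq_len(b), ncol(m) - seq_len(b) + 1)] <- FALSE
      hits <- which(cond, arr.ind = TRUE)
      if (nrow(hits) == 0) next
      gx <- (L[[k]][, c(2:ncol(Io), ncol(Io)), drop = FALSE] -
               L[[k]][, c(1, 1:(ncol(Io) - 1)), drop = FALSE]) / 2
      gy <- (L[[k]][c(2:nrow(Io), nrow(Io)), , drop = FALSE] -
               L[[k]][c(1, 1:(nrow(Io) - 1)), , drop = FALSE]) / 2
      for (i in seq_len(nrow(hits))) {
        r0 <- hits[i, 1]; c0 <- hits[i, 2]
        para <- function(m1, m0, p1) {
          den <- m1 - 2 * m0 + p1
          if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
        }
        ox <- para(m[r0, c0 - 1], m[r0, c0], m[r0, c0 + 1])
        oy <- para(m[r0 - 1, c0], m[r0, c0], m[r0 + 1, c0])
        os <- para(D[[k - 1]][r0, c0], m[r0, c0], D[[k + 1]][r0, c0])
        xo <- (c0 - 1) + ox; yo <- (r0 - 1) + oy
        so <- sig[k] * 2^(os / S)
        ori <- kp_orientation(gx, gy, xo, yo, so)
        dsc <- kp_descriptor(gx, gy, xo, yo, so, ori)
        if (is.null(dsc)) next
        fac <- 2^o
        rows[[length(rows) + 1]] <-
          c(x = unname((xo + 0.5) * fac - 0.5),
            y = unname((yo + 0.5) * fac - 0.5),
            scale = unname(so * fac), orientation = unname(ori),
            response = unname(m[r0, c0]))
        descs[[length(descs) + 1]] <- dsc
      }
    }
    Io <- .resize_area(L[[S + 1]], nrow(Io) %/% 2L, ncol(Io) %/% 2L)
  }
  if (length(rows) == 0) return(empty_keypoints())
  tab <- as.data.frame(do.call(rbind, rows))
  dm <- do.call(rbind, descs)
  ord <- order(-tab$response)
  if (length(ord) > max_keypoints) ord <- ord[seq_len(max_keypoints)]
  structure(list(table = tab[ord, , drop = FALSE],
                 desc = dm[ord, , drop = FALSE]),
            class = "Keypoints")
}

#' @export
print.Keypoints <- function(x, ...) {
  cat(sprintf("<Keypoints> %d keypoints (scales %s)\n", nrow(x$table),
              if (nrow(x$table)) paste0(signif(range(x$table$scale), 3),
                                        collapse = " - ") else "-"))
  invisible(x)
}
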