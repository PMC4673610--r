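#' Segment gold micro-islands from a grayscale image
#'
#' Separates the gold micro-pattern (foreground) from the glass background
#' with a two-class variance-maximising histogram threshold (Otsu's
#' criterion). Gold appears dark in bright-field and bright under the SEM
#' back-scatter detector, so under `polarity = "auto"` the foreground side
#' of the threshold is resolved from the image modality.
#'
#' @param image a [raster_image()] (single-plane grayscale) or matrix.
#' @param polarity `"auto"` (resolve from modality: brightfield -> dark
#'   foreground, backscatter/sem/fluorescence/binary -> bright foreground),
#'   `"dark_foreground"` or `"bright_foreground"`.
#' @return a `PatternMask`: list with `mask` (logical matrix, `TRUE` =
#'   gold), `threshold`, `polarity`, `source_modality` and a `warning`
#'   field (`NA` or a message). A constant image yields an empty mask plus
#'   a warning flag, not an error.
#' @export
segment_pattern <- function(image,
                            polarity = c("auto", "dark_foreground",
                                         "bright_foreground")) {
  polarity <- match.arg(polarity)
  modality <- if (inherits(image, "RasterImage")) image$modality else
    "brightfield"
  px <- as_pixel_matrix(image)
  if (polarity == "auto")
    polarity <- if (modality == "brightfield") "dark_foreground" else
      "bright_foreground"
  rng <- range(px)
  if (diff(rng) == 0) {
    return(structure(list(mask = matrix(FALSE, nrow(px), ncol(px)),
                          threshold = NA_real_, polarity = polarity,
                          source_modality = modality,
                          warning = "constant image: no contrast to segment"),
                     class = "PatternMask"))
  }
  thr <- otsu_threshold(px)
  mask <- if (polarity == "dark_foreground") px <= thr else px > thr
  structure(list(mask = mask, threshold = thr, polarity = polarity,
                 source_modality = modality, warning = NA_character_),
            class = "PatternMask")
}

#' @export
print.PatternMask <- function(x, ...) {
  cat(sprintf("<PatternMask> %d x %d px, %d foreground px, threshold %s (%s)\n",
              ncol(x$mask), nrow(x$mask), sum(x$mask),
              format(x$threshold), x$polarity))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

# Wrap a logical matrix as a PatternMask (used by the synthetic pipelines).
pattern_mask <- function(mask, modality = "binary") {
  structure(list(mask = mask, threshold = NA_real_,
                 polarity = "bright_foreground", source_modality = modality,
                 warning = NA_character_),
            class = "PatternMask")
}

as_mask_matrix <- function(x) {
  if (inherits(x, "PatternMask")) return(x$mask)
  px <- as_pixel_matrix(x)
  px > 0
}

# Otsu's threshold on a 256-bin histogram of the intensity range. Returns
# the cut value on the original intensity scale; foreground/background
# split is `<= thr` vs `> thr`.
otsu_threshold <- function(px) {
  v <- as.vector(px)
  rng <- range(v)
  nb <- 256L
  # integer-valued 8-bit images bin exactly at integer boundaries
  brk <- seq(rng[1], rng[2], length.out = nb + 1)
  h <- tabulate(pmin(findInterval(v, brk, rightmost.closed = TRUE), nb),
                nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (brk[-1] + brk[-(nb + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  brk[k + 1]
}

#' Label micro-islands and compute their morphometrics
#'
#' 8-connected components of a binary pattern mask, with area (pixels and
#' um^2), chain-code perimeter, circularity `4*pi*area / perimeter^2`
#' (clipped at 1, since discretisation can exceed it) and sub-pixel
#' centroid. Islands are labelled 1..n by decreasing pixel count, ties
#' broken by the top-left-most centroid.
#'
#' @param mask a `PatternMask`, logical matrix or binary image.
#' @param pixel_size_nm physical pixel size in nm (for `area_um2`).
#' @param min_area_px drop components smaller than this many pixels
#'   (default 20, to suppress segmentation speckle).
#' @param exclude_border drop islands touching the image border (the
#'   cumulative-distribution CLI defaults to `TRUE`; the function default
#'   is `FALSE` so that pixel bookkeeping stays exact).
#' @return a `data.frame` (class `IslandTable`) with columns `label`,
#'   `pixel_count`, `area_um2`, `perimeter_px`, `circularity`,
#'   `centroid_x`, `centroid_y`; the relabelled component image is
#'   attached as attribute `label_map`, the pixel size as
#'   `pixel_size_nm`.
#' @export
label_islands <- function(mask, pixel_size_nm = NULL, min_area_px = 20,
                          exclude_border = FALSE) {
  m <- as_mask_matrix(mask)
  if (is.null(pixel_size_nm) && inherits(mask, "RasterImage"))
    pixel_size_nm <- mask$pixel_size_nm
  empty <- function() {
    tab <- data.frame(label = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), perimeter_px = numeric(0),
                      circularity = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
    attr(tab, "label_map") <- matrix(0L, nrow(m), ncol(m))
    attr(tab, "pixel_size_nm") <- pixel_size_nm
    class(tab) <- c("IslandTable", "data.frame")
    tab
  }
  if (!any(m)) return(empty())
  lab <- .cc_label(matrix(as.integer(m), nrow(m)))
  n <- attr(lab, "n_labels")
  st <- .region_stats(lab, n)
  per <- .perimeters(lab, n)
  cnt <- st$count
  cx <- st$sum_x / cnt
  cy <- st$sum_y / cnt
  keep <- cnt >= max(min_area_px, 1)
  if (exclude_border)
    keep <- keep & st$xmin > 0 & st$ymin > 0 &
      st$xmax < ncol(m) - 1 & st$ymax < nrow(m) - 1
  if (!any(keep)) return(empty())
  idx <- which(keep)
  ord <- idx[order(-cnt[idx], cy[idx], cx[idx])]
  px_um <- if (is.null(pixel_size_nm)) NA_real_ else (pixel_size_nm / 1000)^2
  tab <- data.frame(
    label = seq_along(ord),
    pixel_count = as.integer(cnt[ord]),
    area_um2 = cnt[ord] * px_um,
    perimeter_px = per[ord],
    circularity = pmin(1, 4 * pi * cnt[ord] / per[ord]^2),
    centroid_x = cx[ord],
    centroid_y = cy[ord])
  # relabel the component image to the sorted order
  remap <- integer(n)
  remap[ord] <- seq_along(ord)
  lm <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  lm[nz] <- remap[lab[nz]]
  attr(tab, "label_map") <- lm
  attr(tab, "pixel_size_nm") <- pixel_size_nm
  class(tab) <- c("IslandTable", "data.frame")
  tab
}

#' Cumulative distributions of island area and circularity
#'
#' Empirical cumulative distributions over the islands of a pattern, the
#' kind of curve used to characterise a stochastic micro-pattern (area
#' spectrum and shape regularity).
#'
#' @param table an `IslandTable` from [label_islands()].
#' @return list with `area` and `circularity` (each a `data.frame` with
#'   sorted `value` and cumulative fraction `cum`, final value exactly 1)
#'   and `summary` (min/median/max of both quantities).
#' @export
island_statistics <- function(table) {
  if (nrow(table) == 0)
    stop("empty island table: no distribution to compute", call. = FALSE)
  cdf <- function(v) {
    v <- sort(v)
    data.frame(value = v, cum = seq_along(v) / length(v))
  }
  area_col <- if (all(is.na(table$area_um2))) table$pixel_count else
    table$area_um2
  list(area = cdf(area_col),
       circularity = cdf(table$circularity),
       summary = list(
         area = c(min = min(area_col), median = median(area_col),
                  max = max(area_col)),
         circularity = c(min = min(table$circularity),
                         median = median(table$circularity),
                         max = max(table$circularity))))
}
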