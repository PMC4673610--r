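#' 2-D raster image with physical pixel size and modality
#'
#' The common currency of all operations in the package: a plain numeric
#' matrix of intensities plus the physical edge length of one pixel (in nm)
#' and a modality tag. Coordinates are 0-based `(x = column, y = row)` with
#' the origin at the top-left and y increasing downward; angles are degrees,
#' counter-clockwise positive in the displayed image.
#'
#' @param pixels numeric or integer matrix of intensities (8-bit, 16-bit or
#'   unit-interval float scale; the package does not rescale).
#' @param pixel_size_nm physical edge length of one pixel in nm, or `NULL`
#'   when unknown. Must be strictly positive when set.
#' @param modality one of `"brightfield"`, `"backscatter"`, `"fluorescence"`,
#'   `"sem"`, `"binary"`. A `"binary"` image must contain exactly the two
#'   values 0 and its maximum.
#' @return an object of class `RasterImage`: a list with elements `pixels`,
#'   `pixel_size_nm`, `modality`.
#' @examples
#' img <- raster_image(matrix(0:255, 16, 16), pixel_size_nm = 65)
#' dim(img$pixels)
#' @export
raster_image <- function(pixels, pixel_size_nm = NULL,
                         modality = c("brightfield", "backscatter",
                                      "fluorescence", "sem", "binary")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("image must have positive width and height", call. = FALSE)
  if (!is.null(pixel_size_nm)) {
    if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
        !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
      stop("`pixel_size_nm` must be a single strictly positive number",
           call. = FALSE)
  }
  if (modality == "binary") {
    v <- unique(as.vector(pixels))
    if (length(v) > 2 || !all(v %in% c(0, max(v))))
      stop("binary modality requires exactly the two values {0, max}",
           call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 modality = modality),
            class = "RasterImage")
}

#' @export
print.RasterImage <- function(x, ...) {
  cat(sprintf("<RasterImage> %d x %d px, modality %s, pixel size %s\n",
              ncol(x$pixels), nrow(x$pixels), x$modality,
              if (is.null(x$pixel_size_nm)) "unset"
              else paste0(x$pixel_size_nm, " nm")))
  invisible(x)
}

#' @export
dim.RasterImage <- function(x) dim(x$pixels)

#' Objective magnification to camera pixel size
#'
#' Pixel sizes of a 2,048 x 2,048 sCMOS camera with 6.5 um pixels behind
#' standard objectives: 65 nm at 100x down to 1,625 nm at 4x. Used to
#' convert between objective choice and physical scale, and to derive the
#' rescale factors of the efficiency benchmark.
#'
#' @return named numeric vector, names are magnifications ("100", "60",
#'   "40", "20", "10", "4"), values the pixel size in nm.
#' @examples
#' magnification_table()[["100"]]  # 65 nm
#' @export
magnification_table <- function() {
  c("100" = 65, "60" = 108, "40" = 162.5, "20" = 325, "10" = 650,
    "4" = 1625)
}

#' Rescale factors relative to the 100x objective
#'
#' @param magnifications magnifications to look up (numeric or character);
#'   defaults to all six table entries.
#' @return named numeric vector of factors (pixel size / 65 nm);
#'   factor(100x) = 1 and factors increase as magnification decreases.
#' @export
magnification_scale_factors <- function(magnifications = NULL) {
  tab <- magnification_table()
  if (is.null(magnifications)) magnifications <- names(tab)
  key <- as.character(magnifications)
  if (!all(key %in% names(tab)))
    stop("unknown magnification(s): ",
         paste(setdiff(key, names(tab)), collapse = ", "), call. = FALSE)
  out <- tab[key] / tab[["100"]]
  names(out) <- key
  out
}
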