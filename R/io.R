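#' Read a raster image from TIFF or PNG
#'
#' Reads a single-plane grayscale image (8- or 16-bit TIFF, 8-bit PNG) and
#' attaches pixel-size and modality metadata. Multi-channel (RGB) inputs
#' must be split by channel index.
#'
#' @param path file path; format detected from the file signature.
#' @param pixel_size_nm optional physical pixel size in nm; when `NULL` the
#'   TIFF resolution tags are used if present.
#' @param modality modality tag, see [raster_image()].
#' @param channel 1-based channel index for multi-channel inputs
#'   (1 = red, 2 = green, 3 = blue); required for RGB files.
#' @return a [raster_image()] with intensities preserved bit-exactly.
#' @export
read_raster <- function(path, pixel_size_nm = NULL,
                        modality = "brightfield", channel = NULL) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  sig <- readBin(path, "raw", n = 8)
  dec <- if (length(sig) >= 8 &&
             identical(sig, as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))) {
    read_png(path)
  } else if (length(sig) >= 4 &&
             rawToChar(sig[1:2]) %in% c("II", "MM")) {
    read_tiff(path)
  } else {
    stop("'", path, "' is neither a TIFF nor a PNG file", call. = FALSE)
  }
  px <- dec$pixels
  if (length(dim(px)) == 3) {
    if (is.null(channel))
      stop("'", path, "' has ", dim(px)[3],
           " channels; pass `channel` to select one", call. = FALSE)
    if (channel < 1 || channel > dim(px)[3])
      stop("channel ", channel, " out of range", call. = FALSE)
    px <- px[, , channel]
  }
  if (is.null(pixel_size_nm)) pixel_size_nm <- dec$pixel_size_nm
  raster_image(px, pixel_size_nm = pixel_size_nm, modality = modality)
}

#' Write a raster image as TIFF or PNG
#'
#' TIFF output is uncompressed grayscale (8- or 16-bit chosen from the data
#' range unless `bits` is given); PNG output is 8-bit grayscale. The pixel
#' size, when known, is stored in the TIFF resolution tags.
#'
#' @param image a [raster_image()], [pattern_mask] or plain matrix.
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.png`).
#' @param bits force 8 or 16 bits per sample (TIFF only).
#' @return the path, invisibly.
#' @export
write_raster <- function(image, path, bits = NULL) {
  px <- as_pixel_matrix(image)
  if (inherits(image, "PatternMask")) px <- px * 255
  psnm <- if (inherits(image, "RasterImage")) image$pixel_size_nm else NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff(px, path, bits = bits, pixel_size_nm = psnm)
  } else if (ext == "png") {
    write_png(px, path)
  } else {
    stop("unsupported output format: '.", ext, "' (use .tif or .png)",
         call. = FALSE)
  }
  invisible(path)
}

#' Write a similarity transform as a JSON record
#'
#' The record holds `{scale, rotation_deg, tx_px, ty_px, score}` at full
#' double precision; [read_transform()] reproduces the values to at least
#' 12 significant digits.
#'
#' @param transform a [similarity_transform()] (optionally carrying a
#'   `score` field) or a list with the fields above.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_transform <- function(transform, path) {
  tr <- as_similarity_transform(transform)
  score <- if (!is.null(transform$score)) transform$score else NA_real_
  if (!all(is.finite(c(tr$scale, tr$rotation_deg, tr$t))) ||
      (!is.finite(score) && !identical(is.na(score) && !is.nan(score),
                                       TRUE)))
    stop("transform fields must be finite", call. = FALSE)
  rec <- list(scale = tr$scale, rotation_deg = tr$rotation_deg,
              tx_px = tr$t[1], ty_px = tr$t[2], score = score)
  extra <- transform[setdiff(names(transform),
                             c("scale", "rotation_deg", "t", "tx_px",
                               "ty_px", "score", "shift"))]
  rec <- c(rec, extra)
  ok <- tryCatch({
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write transform to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a similarity transform written by [write_transform()]
#'
#' @param path JSON file path.
#' @return a [similarity_transform()] with any extra fields (e.g. `score`,
#'   `status`) attached.
#' @export
read_transform <- function(path) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- similarity_transform(scale = rec$scale,
                             rotation_deg = rec$rotation_deg,
                             t = c(rec$tx_px, rec$ty_px))
  for (nm in setdiff(names(rec),
                     c("scale", "rotation_deg", "tx_px", "ty_px")))
    tr[[nm]] <- rec[[nm]]
  tr
}
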