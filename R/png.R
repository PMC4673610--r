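# Minimal 8-bit PNG codec (grayscale and RGB). zlib streams come from base
# R's memCompress()/memDecompress(); only chunk CRC32 and scanline
# (un)filtering are implemented here.

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1] <- c
  }
  .crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  c <- bitwXor(c, -1L)
  u <- as.numeric(c)
  if (u < 0) u <- u + 2^32
  u
}

u32_bytes <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

bytes_u32 <- function(b) {
  v <- as.numeric(as.integer(b))
  v[1] * 16777216 + v[2] * 65536 + v[3] * 256 + v[4]
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), body, u32_bytes(crc32(body)))
}

write_png <- function(pixels, path) {
  px <- round(pixels)
  if (any(px < 0) || any(px > 255))
    stop("PNG writer supports 8-bit values only", call. = FALSE)
  h <- nrow(px); w <- ncol(px)
  # scanlines with filter byte 0
  rows <- matrix(as.raw(t(px)), nrow = w)
  stream <- as.raw(rbind(matrix(raw(1), 1, h), rows))
  ihdr <- c(u32_bytes(w), u32_bytes(h), as.raw(c(8, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(stream, "gzip")),
           png_chunk("IEND", raw(0)))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

read_png <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  if (length(raw) < 8 || !identical(raw[1:8], sig))
    stop("'", path, "' is not a PNG file", call. = FALSE)
  pos <- 8
  idat <- raw(0)
  w <- h <- depth <- coltype <- NULL
  while (pos + 8 <= length(raw)) {
    len <- bytes_u32(raw[(pos + 1):(pos + 4)])
    type <- rawToChar(raw[(pos + 5):(pos + 8)])
    data <- if (len > 0) raw[(pos + 9):(pos + 8 + len)] else raw(0)
    if (type == "IHDR") {
      w <- bytes_u32(data[1:4]); h <- bytes_u32(data[5:8])
      depth <- as.integer(data[9]); coltype <- as.integer(data[10])
      if (as.integer(data[13]) != 0)
        stop("interlaced PNG is not supported", call. = FALSE)
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12 + len
  }
  if (is.null(w)) stop("PNG without IHDR", call. = FALSE)
  if (depth != 8)
    stop("unsupported PNG bit depth: ", depth, "-bit (only 8-bit supported)",
         call. = FALSE)
  if (!coltype %in% c(0L, 2L))
    stop("unsupported PNG color type ", coltype,
         " (grayscale or RGB only)", call. = FALSE)
  ch <- if (coltype == 0L) 1L else 3L
  stream <- as.integer(memDecompress(idat, "gzip"))
  stride <- w * ch
  out <- matrix(0L, nrow = h, ncol = stride)
  prev <- integer(stride)
  for (r in seq_len(h)) {
    off <- (r - 1) * (stride + 1)
    ft <- stream[off + 1]
    line <- stream[(off + 2):(off + 1 + stride)]
    left <- function(v) c(integer(ch), v[seq_len(stride - ch)])
    rec <- switch(as.character(ft),
      "0" = line,
      "1" = { v <- line
              for (i in (ch + 1):stride) v[i] <- (v[i] + v[i - ch]) %% 256
              v },
      "2" = (line + prev) %% 256,
      "3" = { v <- line
              for (i in seq_len(stride)) {
                a <- if (i > ch) v[i - ch] else 0L
                v[i] <- (v[i] + (a + prev[i]) %/% 2) %% 256
              }
              v },
      "4" = { v <- line
              for (i in seq_len(stride)) {
                a <- if (i > ch) v[i - ch] else 0L
                cc <- if (i > ch) prev[i - ch] else 0L
                v[i] <- (v[i] + paeth(a, prev[i], cc)) %% 256
              }
              v },
      stop("unsupported PNG filter type ", ft, call. = FALSE))
    out[r, ] <- rec
    prev <- rec
  }
  if (ch == 1L) {
    list(pixels = out, bits = 8L)
  } else {
    arr <- array(0L, c(h, w, 3))
    for (k in 1:3) arr[, , k] <- out[, seq(k, stride, by = 3)]
    list(pixels = arr, bits = 8L)
  }
}
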