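test_that("TIFF and PNG round trips are bit-exact", {
  m16 <- matrix(sample(0:65535, 48 * 64, replace = TRUE), 48, 64)
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(raster_image(m16, pixel_size_nm = 325), f)
  r <- read_raster(f, modality = "brightfield")
  expect_identical(r$pixels, m16)
  expect_equal(r$pixel_size_nm, 325, tolerance = 1e-6)

  chk <- matrix(c(0, 255, 255, 0), 2, 2)[rep(1:2, 2), rep(1:2, 2)]
  fp <- withr::local_tempfile(fileext = ".png")
  write_raster(raster_image(chk), fp)
  r2 <- read_raster(fp)
  expect_identical(r2$pixels + 0, chk)
  expect_setequal(unique(as.vector(r2$pixels)), c(0, 255))

  m8 <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  f8 <- withr::local_tempfile(fileext = ".tif")
  write_raster(raster_image(m8), f8, bits = 8)
  expect_identical(read_raster(f8)$pixels, m8)
})

test_that("RGB inputs are split by channel index (plane-extraction oracle)", {
  set.seed(7)
  planes <- lapply(1:3, function(i)
    matrix(sample(0:255, 64, replace = TRUE), 8, 8))
  # build an RGB PNG through the codec internals (interleaved samples)
  h <- 8L; w <- 8L
  inter <- array(0L, c(h, w, 3))
  for (k in 1:3) inter[, , k] <- planes[[k]]
  stream <- raw(0)
  for (r in 1:h) {
    row <- as.vector(t(cbind(inter[r, , 1], inter[r, , 2], inter[r, , 3])))
    stream <- c(stream, as.raw(0), as.raw(row))
  }
  ihdr <- c(clemalign:::u32_bytes(w), clemalign:::u32_bytes(h),
            as.raw(c(8, 2, 0, 0, 0)))
  f <- withr::local_tempfile(fileext = ".png")
  con <- file(f, "wb")
  writeBin(c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             clemalign:::png_chunk("IHDR", ihdr),
             clemalign:::png_chunk("IDAT", memCompress(stream, "gzip")),
             clemalign:::png_chunk("IEND", raw(0))), con)
  close(con)
  expect_error(read_raster(f), "channels")
  for (k in 1:3)
    expect_identical(read_raster(f, channel = k)$pixels, planes[[k]])
})

test_that("unreadable inputs fail with informative errors", {
  expect_error(read_raster(file.path(tempdir(), "does-not-exist.tif")),
               "not found")
  f <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.raw(1:32), f)
  expect_error(read_raster(f), "neither a TIFF nor a PNG")
  # depth guard on write
  expect_error(write_tiff <- clemalign:::write_tiff(matrix(0, 2, 2), f,
                                                    bits = 32L), "32-bit")
})

test_that("raster_image validates its invariants", {
  expect_error(raster_image(matrix(numeric(0), 0, 0)), "positive")
  expect_error(raster_image(matrix(0, 2, 2), pixel_size_nm = -1),
               "positive")
  expect_error(raster_image(matrix(c(0, 1, 2, 3), 2), modality = "binary"),
               "binary")
  ok <- raster_image(matrix(c(0, 255, 0, 255), 2), modality = "binary")
  expect_s3_class(ok, "RasterImage")
})

test_that("magnification table matches the camera optics", {
  tab <- magnification_table()
  expect_length(tab, 6)
  # pixel size strictly decreases as magnification increases
  mags <- as.numeric(names(tab))
  expect_true(all(diff(tab[order(mags)]) < 0))
  expect_equal(unname(tab[["100"]]), 65)
  # a 20 px dot at the 100x sampling is 1.3 um across
  expect_equal(20 * tab[["100"]] / 1000, 1.3)
  f <- magnification_scale_factors()
  expect_equal(unname(f[["100"]]), 1)
  expect_true(all(diff(f[order(as.numeric(names(f)))]) < 0))
})

test_that("transform records survive the JSON round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  id <- similarity_transform()
  write_transform(id, f)
  back <- read_transform(f)
  expect_equal(back$scale, 1)
  expect_equal(back$rotation_deg, 0)
  expect_equal(back$t, c(0, 0))

  tr <- similarity_transform(2, 15, c(40, -7))
  tr$scale <- tr$scale + pi * 1e-13  # exercise full precision
  write_transform(tr, f)
  back <- read_transform(f)
  expect_equal(back$scale, tr$scale, tolerance = 1e-12)
  expect_equal(back$rotation_deg, 15, tolerance = 1e-12)
  expect_equal(back$t, c(40, -7), tolerance = 1e-12)

  bad <- similarity_transform(2, 15, c(40, -7))
  bad$rotation_deg <- NaN
  expect_error(write_transform(bad, f), "finite")
})

test_that("similarity transforms compose and invert to identity", {
  tr <- similarity_transform(1.7, 33, c(12.5, -3.25))
  id <- compose_similarity(tr, invert_similarity(tr))
  expect_equal(id$scale, 1, tolerance = 1e-9)
  expect_equal(id$rotation_deg, 0, tolerance = 1e-9)
  expect_equal(id$t, c(0, 0), tolerance = 1e-9)
  p <- cbind(c(0, 10, -4.5), c(3, -2, 8))
  q <- apply_similarity(tr, p)
  expect_equal(apply_similarity(invert_similarity(tr), q), p,
               tolerance = 1e-9, ignore_attr = TRUE)
})
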