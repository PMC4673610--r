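test_that("dot matrix generation hits the target coverage (pixel-count oracle)", {
  gen <- generate_dot_matrix(dot_matrix_spec(1024, 1024, small_dot_mix(),
                                             0.10, seed = 7))
  measured <- mean(gen$image$pixels > 0)
  expect_equal(measured, gen$coverage)
  expect_gte(measured, 0.09); expect_lte(measured, 0.11)
  expect_true(all(gen$image$pixels %in% c(0L, 255L)))
  expect_equal(gen$image$pixel_size_nm, 65)
  # mixed diameters contribute (near-)equal shares of nominal dot area,
  # so small dots are numerous and large dots rare
  gen2 <- generate_dot_matrix(dot_matrix_spec(1024, 1024, c(8, 14, 22, 40),
                                              0.10, seed = 2))
  areas <- tapply(pi * (gen2$dots$diameter_px / 2)^2,
                  gen2$dots$diameter_px, sum)
  expect_equal(length(areas), 4)
  expect_lt(max(areas) / min(areas), 1 + pi * 40^2 / 4 / min(areas))
  expect_gt(sum(gen2$dots$diameter_px == 8),
            sum(gen2$dots$diameter_px == 40))

  # zero coverage -> blank matrix
  blank <- generate_dot_matrix(dot_matrix_spec(64, 64, c(8), 0, seed = 1))
  expect_equal(sum(blank$image$pixels), 0)

  expect_error(dot_matrix_spec(100, 100, c(1, 8)), ">= 2 px")
  expect_error(dot_matrix_spec(100, 100, 8, 1.2), "target_coverage")
})

test_that("crop_pairs bookkeeping matches the pixels", {
  gen <- generate_dot_matrix(dot_matrix_spec(900, 900, c(8, 14, 22),
                                             0.10, seed = 8))
  # full overlap -> identical tiles, zero shift
  p1 <- crop_pairs(gen$image, 2, overlap = 1, tile = 256, seed = 1)
  expect_equal(p1[[1]]$true_shift, c(0, 0))
  expect_identical(p1[[1]]$a, p1[[1]]$b)

  # axis mode at 90% overlap: |shift| = round(0.10 * tile) on one axis
  p2 <- crop_pairs(gen$image, 6, overlap = 0.90, shift_mode = "axis",
                   tile = 512, seed = 2)
  for (p in p2) {
    s <- p$true_shift
    expect_equal(sort(abs(s)), c(0, 51))
    # the recorded shift is the crop-coordinate difference: a[r, c] equals
    # b[r - sy, c - sx] over the whole overlap strip (bookkeeping oracle)
    rs <- (max(1, 1 + s[2])):(min(512, 512 + s[2]))
    cs <- (max(1, 1 + s[1])):(min(512, 512 + s[1]))
    expect_identical(p$a[rs, cs], p$b[rs - s[2], cs - s[1]])
  }
  # free mode varies both components across pairs
  p3 <- crop_pairs(gen$image, 8, overlap = 0.90, shift_mode = "free",
                   tile = 512, seed = 3)
  shifts <- t(vapply(p3, function(p) p$true_shift, numeric(2)))
  expect_gt(nrow(unique(shifts)), 1)
  expect_true(all(abs(shifts) <= 51))
  expect_error(crop_pairs(gen$image, 1, tile = 2048), "exceeds")
})

test_that("degrade: identity settings, size convention, binary output", {
  m <- (disk_mask(40, 256) | disk_mask(12, 256, cx = 40, cy = 40)) * 255
  idcfg <- degradation_config(down_factor = 1, noise_fraction = 0,
                              blur_sigma_px = 0, binarize_threshold = 100)
  expect_equal(degrade(m, idcfg), m + 0, ignore_attr = TRUE)

  out <- degrade(m, degradation_config(), seed = 5)
  expect_equal(dim(out), c(256, 256))
  expect_setequal(unique(as.vector(out)), c(0, 255))
  # floor size convention at the reduced scale: floor(256 / 3.846) = 66
  expect_equal(attr(out, "reduced_dim"), c(66L, 66L))
  expect_equal(floor(2048 / 3.846), 532)  # the camera-tile case

  # area preservation: dots >= 20 px change by < 10% under paper settings
  gen <- generate_dot_matrix(dot_matrix_spec(768, 768, c(24, 48, 96),
                                             0.10, seed = 9))
  tile <- gen$image$pixels
  deg <- degrade(tile, degradation_config(), seed = 6)
  expect_lt(abs(sum(deg > 0) / sum(tile > 0) - 1), 0.10)
})

test_that("accuracy run: exact recovery without degradation, reproducibility", {
  spec <- dot_matrix_spec(1024, 1024, small_dot_mix()[1:5], 0.10, seed = 5)
  # integer true shifts (scale factor exactly 1), no degradation -> 0 error
  rep0 <- run_accuracy(spec, n_base_pairs = 6, n_scale_factors = 2,
                       scale_range = c(1, 1), config = NULL, seed = 11,
                       tile = 256, quiet = TRUE)
  expect_equal(rep0$mean_deviation, 0)
  expect_equal(rep0$n_failed, 0)

  # byte-reproducible for a fixed seed
  repA <- run_accuracy(spec, n_base_pairs = 4, n_scale_factors = 2,
                       seed = 12, tile = 256, quiet = TRUE)
  repB <- run_accuracy(spec, n_base_pairs = 4, n_scale_factors = 2,
                       seed = 12, tile = 256, quiet = TRUE)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write.csv(repA$records, fa, row.names = FALSE)
  write.csv(repB$records, fb, row.names = FALSE)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # records carry the documented fields
  expect_true(all(c("pair_id", "scale_factor", "true_dx", "true_dy",
                    "est_dx", "est_dy", "err_x", "err_y",
                    "total_deviation", "success") %in%
                    names(repA$records)))
  expect_true(all(repA$records$total_deviation >= 0))
})

test_that("island loss deletes whole islands at the requested rate", {
  set.seed(33)
  m <- matrix(FALSE, 400, 400)
  centers <- expand.grid(x = seq(20, 380, by = 60),
                         y = seq(20, 380, by = 60))[1:40, ]
  for (i in 1:40)
    m <- m | disk_mask(7, 400, cx = centers$x[i], cy = centers$y[i])
  n0 <- nrow(label_islands(m, min_area_px = 1))
  expect_equal(n0, 40)
  # fraction 0: no-op
  keep <- simulate_island_loss(m, 0, seed = 1)
  expect_identical(keep$mask$mask, m)
  # 40 islands at 5%: exactly 2 removed (component-count oracle)
  thin <- simulate_island_loss(m, 0.05, seed = 2)
  expect_equal(length(thin$deleted_labels), 2)
  expect_equal(nrow(label_islands(thin$mask, min_area_px = 1)), 38)
  expect_error(simulate_island_loss(m, 1), "fraction")
})

test_that("blank matrices give zero efficiency everywhere", {
  specs <- list(dot_matrix_spec(600, 600, c(8), 0, seed = 1))
  rep <- run_efficiency(specs, magnifications = c(100, 20), n_pairs = 2,
                        tile = 256, seed = 1, quiet = TRUE)
  expect_equal(rep$efficiency, c(0, 0))
  expect_equal(rep$n_success, c(0L, 0L))
})

test_that("seed splitting is deterministic and in integer range", {
  s <- vapply(1:50, function(k) clemalign:::split_seed(123, k), numeric(1))
  expect_true(all(s == floor(s)))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 50)
  expect_identical(clemalign:::split_seed(7, 3),
                   clemalign:::split_seed(7, 3))
})
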