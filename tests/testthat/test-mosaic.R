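test_that("phase correlation recovers cyclic shifts exactly", {
  set.seed(1)
  a <- matrix(as.numeric(runif(64 * 64) > 0.5), 64)
  # b carries the content of a displaced by (dx, dy) = (5, -3)
  b <- a[((0:63 - 3) %% 64) + 1, ((0:63 + 5) %% 64) + 1]
  est <- phase_correlate(a, b)
  expect_equal(c(est$dx, est$dy), c(5, -3))
  # identical images: zero shift, maximal score
  same <- phase_correlate(a, a)
  expect_equal(c(same$dx, same$dy), c(0, 0))
  expect_gte(same$score, est$score)
  expect_equal(same$score, 1, tolerance = 1e-6)
})

test_that("phase correlation agrees with the brute-force NCC oracle", {
  set.seed(42)
  for (i in 1:5) {
    a <- matrix(as.numeric(runif(64 * 64) > 0.5), 64)
    dx <- sample(-20:20, 1); dy <- sample(-20:20, 1)
    b <- a[((0:63 + dy) %% 64) + 1, ((0:63 + dx) %% 64) + 1]
    flip <- sample(length(b), round(0.05 * length(b)))
    b[flip] <- 1 - b[flip]
    est <- phase_correlate(a, b)
    oracle <- brute_force_shift(a, b)
    expect_equal(c(est$dx, est$dy), oracle)
    expect_equal(c(est$dx, est$dy), c(dx, dy))
  }
})

test_that("score decreases monotonically with replacement noise", {
  set.seed(9)
  a <- matrix(as.numeric(runif(96 * 96) > 0.5), 96)
  scores <- vapply(c(0, 0.2, 0.4), function(fr) {
    b <- a
    if (fr > 0) {
      idx <- sample(length(b), round(fr * length(b)))
      b[idx] <- as.numeric(runif(length(idx)) > 0.5)
    }
    phase_correlate(a, b)$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("phase correlation properties: antisymmetry, degenerate guard", {
  set.seed(11)
  for (i in 1:5) {
    a <- matrix(runif(48 * 80), 48)
    b <- matrix(runif(48 * 80), 48)
    # correlated pair: b = shifted a + noise
    b <- 0.7 * a[((0:47 - 4) %% 48) + 1, ((0:79 - 7) %% 80) + 1] + 0.3 * b
    f <- phase_correlate(a, b); g <- phase_correlate(b, a)
    expect_equal(c(f$dx, f$dy), -c(g$dx, g$dy))
    expect_equal(f$score, g$score, tolerance = 1e-9)
    expect_lt(abs(f$dx), 80); expect_lt(abs(f$dy), 48)
  }
  expect_error(phase_correlate(matrix(1, 8, 8), matrix(runif(64), 8)),
               "degenerate")
  expect_error(phase_correlate(matrix(runif(64), 8), matrix(runif(32), 4)),
               "shape")
})

test_that("sub-pixel refinement stays within half a pixel", {
  set.seed(2)
  a <- island_pattern(128, c(8, 12), 0.12, seed = 2) + 0
  # warp moves content by +t, so b(x) = a(x - t) and the estimate is -t
  sh <- clemalign:::.warp_similarity(a, 128, 128, 1, 0, 3.4, -2.6,
                                     0, 0, 0, 0, TRUE, 0)
  est <- phase_correlate(a, sh, subpixel = TRUE)
  expect_equal(est$dx + est$dx_sub, -3.4, tolerance = 0.5)
  expect_equal(est$dy + est$dy_sub, 2.6, tolerance = 0.5)
})

test_that("single-tile stitching is the identity", {
  m <- island_pattern(64, c(6, 10), 0.15, seed = 4) * 255
  gm <- stitch_grid(tile_set(list(m), 1, 1))
  expect_equal(gm$image$pixels, m)
  expect_equal(unlist(gm$offsets[, c("resolved_x", "resolved_y")]),
               c(resolved_x = 0, resolved_y = 0))
})

test_that("2x2 cut-and-reassemble reconstructs the master exactly", {
  set.seed(8)
  master <- island_pattern(600, c(10, 16, 26), 0.12, seed = 8) * 255
  ov <- 0.30
  side <- 300  # 2x2 tiles with 30% overlap: step 210
  step <- round(side * (1 - ov))
  cut <- function(x0, y0) master[y0 + (1:side), x0 + (1:side)]
  tiles <- list(cut(0, 0), cut(step, 0), cut(0, step), cut(step, step))
  # perturb the nominal offsets by +/- 3 px; correlation must recover
  nominal <- cbind(c(0, step, 0, step), c(0, 0, step, step)) +
    matrix(sample(-3:3, 8, replace = TRUE), 4, 2)
  ts <- tile_set(tiles, 2, 2, overlap = ov, nominal_offsets = nominal)
  gm <- stitch_grid(ts)
  expect_equal(dim(gm$image$pixels), c(510, 510))
  expect_equal(gm$image$pixels, master[1:510, 1:510])
  # resolved offsets deviate from (unperturbed) nominal by < overlap width
  expect_true(all(abs(gm$offsets$resolved_x - c(0, step, 0, step)) <
                    side * ov))

  # placement is invariant to tile enumeration order
  perm <- c(3, 1, 4, 2)
  ts2 <- tile_set(tiles[perm], 2, 2, overlap = ov,
                  nominal_offsets = nominal[perm, ])
  ts2$grid <- ts$grid[perm, ]
  gm2 <- stitch_grid(ts2)
  expect_equal(gm2$image$pixels, gm$image$pixels)
})

test_that("weak links fall back to nominal placement with a warning", {
  set.seed(5)
  t1 <- matrix(runif(100 * 100), 100)
  t2 <- matrix(runif(100 * 100), 100)  # unrelated content
  ts <- tile_set(list(t1, t2), 1, 2, overlap = 0.3)
  expect_warning(gm <- stitch_grid(ts, score_floor = 0.9), "nominal")
  expect_equal(gm$offsets$resolved_x[2], 70)
})

test_that("embed_highres: crop identity and two-resolution placement", {
  master <- island_pattern(512, c(10, 16, 26), 0.12, seed = 12) * 255
  # scale_ratio 1: tile is an exact crop
  tile <- master[101:228, 141:268]
  base_pad <- master
  res <- embed_highres(base_pad, tile, scale_ratio = 1)
  expect_equal(res$placement, c(140, 100))
  # two-resolution rendering: base sampled 4x coarser than the tile
  base <- clemalign:::.resize_area(master, 128, 128)
  tile2 <- master[129:384, 129:384]   # 256^2 crop at full sampling
  res2 <- embed_highres(base, tile2, scale_ratio = 4)
  expect_lte(max(abs(res2$placement - c(32, 32))), 1)
  # round trip: the placed region matches the downscaled tile within 2%
  small <- clemalign:::.resize_area(tile2, 64, 64)
  region <- base[res2$placement[2] + (1:64), res2$placement[1] + (1:64)]
  expect_lt(mean(abs(region - small)), 0.02 * 255)
  # composited image carries the substituted content
  comp <- res2$composite$pixels
  expect_equal(comp[res2$placement[2] + (1:64), res2$placement[1] + (1:64)],
               small)
  # failure is reported, not guessed
  noise <- matrix(runif(64 * 64) * 255, 64)
  expect_error(embed_highres(base, noise, scale_ratio = 1,
                             score_floor = 0.9), "placement not found")
})
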