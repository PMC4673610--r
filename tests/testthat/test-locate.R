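test_that("keypoint detection: blank images, disks, scale proportionality", {
  expect_equal(nrow(detect_keypoints(matrix(0, 64, 64))$table), 0)
  k20 <- detect_keypoints(disk_mask(20, 256) + 0)
  k40 <- detect_keypoints(disk_mask(40, 256) + 0)
  expect_gte(nrow(k20$table), 1)
  expect_gte(nrow(k40$table), 1)
  # strongest response within 2 px of the construction centre
  expect_lt(sqrt((k20$table$x[1] - 127.5)^2 + (k20$table$y[1] - 127.5)^2), 2)
  expect_lt(sqrt((k40$table$x[1] - 127.5)^2 + (k40$table$y[1] - 127.5)^2), 2)
  # detected scale doubles with the disk radius, within 20%
  ratio <- k40$table$scale[1] / k20$table$scale[1]
  expect_gte(ratio, 1.6); expect_lte(ratio, 2.4)
  # descriptors are unit norm
  expect_equal(sqrt(rowSums(k20$desc^2)), rep(1, nrow(k20$desc)),
               tolerance = 1e-6)
})

test_that("keypoint positions are equivariant under 90 degree rotation", {
  m <- island_pattern(200, c(12, 18, 26), 0.12, seed = 5) + 0
  kA <- detect_keypoints(m)
  # mr[r, c] = m[n + 1 - c, r]: a 90 degree grid rotation under which the
  # original point (x, y) lands at (n - 1 - y, x)
  mr <- t(m)[, nrow(m):1]
  stopifnot(all(dim(mr) == c(200, 200)))
  kB <- detect_keypoints(mr)
  mapped <- cbind(nrow(m) - 1 - kA$table$y, kA$table$x)
  # every strong original keypoint has a rotated counterpart within 1 px
  strong <- kA$table$response >= stats::quantile(kA$table$response, 0.25)
  d <- vapply(which(strong), function(i)
    min(sqrt((kB$table$x - mapped[i, 1])^2 +
             (kB$table$y - mapped[i, 2])^2)), numeric(1))
  expect_gte(mean(d <= 1), 0.9)
})

test_that("descriptor matching: self-match, shuffled bijection, ambiguity", {
  m <- island_pattern(256, c(10, 16, 24), 0.12, seed = 6) + 0
  kp <- detect_keypoints(m)
  n <- nrow(kp$table)
  expect_gte(n, 10)
  self <- match_descriptors(kp, kp, ratio = 1)
  expect_equal(self$query_idx, self$ref_idx)
  expect_equal(self$distance, rep(0, nrow(self)), tolerance = 1e-6)

  # shuffled copy: exhaustive nearest-neighbour oracle recovers the bijection
  perm <- sample(n)
  shuf <- kp
  shuf$table <- kp$table[perm, ]
  shuf$desc <- kp$desc[perm, , drop = FALSE]
  mt <- match_descriptors(shuf, kp, ratio = 1)
  expect_equal(mt$ref_idx, perm[mt$query_idx])
  oracle <- apply(as.matrix(dist(rbind(shuf$desc, kp$desc)))[1:n,
                                                             n + (1:n)],
                  1, which.min)
  expect_equal(unname(oracle[mt$query_idx]), mt$ref_idx)

  # two identical disks: the ratio test rejects matches on them (d1 ~ d2)
  twin <- matrix(0, 128, 256)
  twin[disk_mask(12, 128, cx = 40, cy = 63)] <- 1
  twin[, 129:256][disk_mask(12, 128, cx = 60, cy = 63)] <- 1
  kt <- detect_keypoints(twin)
  expect_gte(nrow(kt$table), 2)
  single <- matrix(0, 128, 128)
  single[disk_mask(12, 128, cx = 70, cy = 50)] <- 1
  ks <- detect_keypoints(single)
  mt2 <- match_descriptors(ks, kt, ratio = 0.8)
  expect_equal(nrow(mt2), 0)
  expect_error(match_descriptors(empty_kp <- detect_keypoints(
    matrix(0, 32, 32)), kt), "non-empty")
})

test_that("estimate_similarity: closed form, identity, planted transform", {
  set.seed(21)
  # exactly two noise-free correspondences -> the analytic similarity
  p <- rbind(c(0, 0), c(10, 0))
  tr0 <- similarity_transform(2, 15, c(40, -7))
  q <- apply_similarity(tr0, p)
  est <- estimate_similarity(p, q, min_inliers = 2)
  expect_equal(est$transform$scale, 2, tolerance = 1e-9)
  expect_equal(est$transform$rotation_deg, 15, tolerance = 1e-9)
  expect_equal(est$transform$t, c(40, -7), tolerance = 1e-9)

  # identity on exact correspondences, all inliers
  pts <- cbind(runif(20, 0, 500), runif(20, 0, 500))
  est_id <- estimate_similarity(pts, pts)
  expect_equal(est_id$status, "located")
  expect_true(all(est_id$inliers))
  expect_equal(est_id$transform$scale, 1, tolerance = 1e-9)

  # 20 inliers under (s=2, th=15, t=(40,-7)) plus 30% gross outliers
  p2 <- cbind(runif(20, 0, 500), runif(20, 0, 500))
  q2 <- apply_similarity(tr0, p2) + matrix(rnorm(40, 0, 0.3), 20)
  p_out <- cbind(runif(9, 0, 500), runif(9, 0, 500))
  q_out <- cbind(runif(9, 0, 1200), runif(9, 0, 1200))
  est2 <- estimate_similarity(rbind(p2, p_out), rbind(q2, q_out), seed = 3)
  expect_equal(est2$status, "located")
  # oracle: least squares on the known-inlier subset
  oracle <- clemalign:::similarity_lsq(p2, q2)
  otr <- clemalign:::ab_to_transform(oracle)
  expect_equal(est2$transform$scale / otr$scale, 1, tolerance = 0.01)
  expect_equal(est2$transform$rotation_deg, otr$rotation_deg,
               tolerance = 0.5)
  expect_lt(max(abs(est2$transform$t - otr$t)), 0.5)
  expect_true(all(est2$inliers[1:20]))

  expect_error(estimate_similarity(p[1, , drop = FALSE],
                                   q[1, , drop = FALSE]), "at least 2")
})

test_that("locate_roi: crop identity, planted similarity, negative control", {
  map <- island_pattern(768, c(10, 14, 20, 28), 0.12, seed = 31)
  # exact crop: offset recovered exactly after rounding
  roi <- map[201:456, 301:556]
  res <- locate_roi(roi, map, seed = 1)
  expect_equal(res$status, "located")
  expect_equal(res$transform$scale, 1, tolerance = 0.005)
  expect_lt(abs(res$transform$rotation_deg %% 360 -
                  c(0, 360)[1 + (res$transform$rotation_deg %% 360 > 180)]),
            0.5)
  expect_equal(round(res$transform$t), c(300, 200))

  # planted similarity with 5% island deletion
  tr <- similarity_transform(0.8, 125, c(380, 330))
  roi2 <- planted_roi(map, 0.8, 125, c(380, 330), n = 384)
  roi2 <- simulate_island_loss(roi2, 0.05, seed = 2)$mask
  res2 <- locate_roi(roi2, map, seed = 2)
  expect_equal(res2$status, "located")
  expect_equal(res2$transform$scale / 0.8, 1, tolerance = 0.01)
  dth <- (res2$transform$rotation_deg - 125 + 180) %% 360 - 180
  expect_lt(abs(dth), 1)
  expect_lt(max(abs(res2$transform$t - c(380, 330))), 2)

  # unrelated pattern: status failed, no transform asserted
  other <- island_pattern(384, c(10, 14, 20), 0.12, seed = 99)
  res3 <- locate_roi(other, map, seed = 3)
  expect_equal(res3$status, "failed")
  expect_null(res3$transform)
})

test_that("voronoi_augment: single site, analytic bisector, labeling oracle", {
  # one centroid: no edges, mask unchanged
  m1 <- disk_mask(8, 64)
  v1 <- voronoi_augment(m1)
  expect_equal(nrow(v1$edge_pixels), 0)
  expect_identical(v1$mask_augmented$mask, m1)

  # two centroids: the edge sits on the perpendicular bisector
  m2 <- matrix(FALSE, 64, 96)
  m2 <- m2 | (outer((0:63 - 31)^2, (0:95 - 20)^2, "+") <= 25)
  m2 <- m2 | (outer((0:63 - 31)^2, (0:95 - 70)^2, "+") <= 25)
  tab <- label_islands(m2, min_area_px = 1)
  v2 <- voronoi_augment(m2, tab)
  expect_gt(nrow(v2$edge_pixels), 0)
  a <- unlist(tab[1, c("centroid_x", "centroid_y")])
  b <- unlist(tab[2, c("centroid_x", "centroid_y")])
  # |d(p,a)^2 - d(p,b)^2| small near the rasterised bisector
  da <- sqrt((v2$edge_pixels$x - a[1])^2 + (v2$edge_pixels$y - a[2])^2)
  db <- sqrt((v2$edge_pixels$x - b[1])^2 + (v2$edge_pixels$y - b[2])^2)
  expect_lt(max(abs(da - db)), 1.5)

  # 25 random sites: the label map equals brute-force nearest-site labeling
  set.seed(17)
  sx <- runif(25, 3, 93); sy <- runif(25, 3, 61)
  m3 <- matrix(FALSE, 64, 96)
  m3[cbind(round(sy) + 1, round(sx) + 1)] <- TRUE
  tab3 <- data.frame(label = 1:25, centroid_x = sx, centroid_y = sy)
  v3 <- voronoi_augment(m3, tab3)
  oracle <- matrix(0L, 64, 96)
  for (r in 1:64) for (c in 1:96)
    oracle[r, c] <- which.min((c - 1 - sx)^2 + (r - 1 - sy)^2)
  expect_equal(v3$label_map, oracle)

  # degenerate: coincident centroids
  bad <- data.frame(label = 1:2, centroid_x = c(5, 5), centroid_y = c(5, 5))
  expect_error(voronoi_augment(m3, bad), "degenerate")
})

test_that("voronoi augmentation strictly increases keypoint count", {
  m <- island_pattern(256, c(12, 20, 30), 0.08, seed = 13)
  tab <- label_islands(m, min_area_px = 5)
  expect_gte(nrow(tab), 3)
  aug <- voronoi_augment(m, tab)
  n0 <- nrow(detect_keypoints(m + 0)$table)
  n1 <- nrow(detect_keypoints(aug$mask_augmented$mask + 0)$table)
  expect_gt(n1, n0)
})

test_that("localisation survives 5% island loss on a map crop", {
  map <- island_pattern(640, c(10, 14, 20, 28), 0.12, seed = 41)
  roi <- map[151:406, 211:466]
  thin <- simulate_island_loss(roi, 0.05, seed = 4)$mask
  res <- locate_roi(thin, map, seed = 4)
  expect_equal(res$status, "located")
  expect_lt(max(abs(res$transform$t - c(210, 150))), 2)
})
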