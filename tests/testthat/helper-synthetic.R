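# Fixture builders shared by the test files. Everything is generated in
# code; nothing binary ships with the package.

# rasterised disk of radius r centred in an n x n logical matrix
disk_mask <- function(r, n = 2 * r + 21, cx = (n - 1) / 2, cy = cx) {
  xs <- 0:(n - 1)
  outer((xs - cy)^2, (xs - cx)^2, "+") <= r^2
}

# random island pattern (logical mask) built from the dot generator
island_pattern <- function(n = 512, diameters = c(12, 18, 26, 40),
                           coverage = 0.12, seed = 0) {
  gen <- generate_dot_matrix(dot_matrix_spec(n, n, diameters, coverage,
                                             seed = seed))
  gen$image$pixels > 0
}

# the reduced mixed-diameter set used on small test matrices in place of
# the 20..1000 px production set (a 1000 px dot exceeds 2048^2 frames)
small_dot_mix <- function() c(8, 12, 20, 40, 64, 100, 200)

# render the ROI view of `map_mask` under the ROI->map similarity
# (scale s, rotation th degrees, translation t), n x n pixels
planted_roi <- function(map_mask, s, th, t, n = 512) {
  inv <- invert_similarity(similarity_transform(s, th, t))
  m <- clemalign:::.warp_similarity(map_mask + 0, n, n, inv$scale,
                                    inv$rotation_deg, inv$t[1], inv$t[2],
                                    0, 0, 0, 0, FALSE, 0)
  m > 0.5
}

# pattern B such that rotating B about its centre by th and shifting by
# (tx, ty) reproduces A (the rotational_align forward model)
planted_rotation <- function(A, th, tx, ty) {
  n <- nrow(A)
  cb <- c((n - 1) / 2, (n - 1) / 2)
  B <- clemalign:::.warp_similarity(A + 0, n, n, 1, -th, 0, 0,
                                    cb[1] + tx, cb[2] + ty, cb[1], cb[2],
                                    TRUE, 0)
  B > 0.5
}

# brute-force normalised cross-correlation over all cyclic integer
# shifts; independent oracle for phase_correlate
brute_force_shift <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  nr <- nrow(a); nc <- ncol(a)
  best <- -Inf; arg <- c(NA, NA)
  for (dy in 0:(nr - 1)) {
    br <- b[((0:(nr - 1) - dy) %% nr) + 1, , drop = FALSE]
    for (dx in 0:(nc - 1)) {
      bs <- br[, ((0:(nc - 1) - dx) %% nc) + 1, drop = FALSE]
      v <- sum(a * bs)
      if (v > best) {
        best <- v
        arg <- c(if (dx > nc / 2) dx - nc else dx,
                 if (dy > nr / 2) dy - nr else dy)
      }
    }
  }
  arg
}
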