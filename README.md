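# clemalign

Registration toolbox for **correlative light–electron microscopy (CLEM)**
with stochastic gold micro-pattern fiducials.

CLEM images the same cell twice — by fluorescence light microscopy, then
by scanning electron microscopy — and the two instruments share no
coordinate system: the sample is remounted with arbitrary rotation,
translation and magnification between them. A random pattern of gold
micro-islands sputtered onto the coverslip is visible in both modalities
(dark in bright-field, bright under the back-scatter detector) and serves
as a common reference. `clemalign` provides the image-analysis pipeline
for that workflow, for microscopists and image-analysis folk who want a
scriptable, dependency-light implementation:

* **segmentation** of gold islands (Otsu threshold, modality-aware
  polarity) and island morphometrics — area, chain-code perimeter,
  circularity `4πA/P²`, sub-pixel centroids;
* **stitching** of bright-field tiles into a whole-coverslip *global map*
  by phase correlation on overlap strips with a maximum-score spanning
  placement;
* **ROI localisation** on the global map under unknown similarity
  transform `p' = s·R(θ)·p + t`, via a from-scratch scale-space blob
  detector (determinant-of-Hessian pyramid), oriented 4×4-cell gradient
  descriptors, Lowe-ratio + mutual-best matching and 2-point RANSAC;
* **rotation alignment** of bright-field vs back-scatter patterns: a
  full-circle rotation sweep (2° coarse, 0.1° refinement) scored by the
  phase-correlation peak, plus fusion of fluorescence channels into
  electron-microscope coordinates;
* a **synthetic random-dot benchmark** that reproduces the published
  validation of this class of pipeline: alignment *efficiency* across
  dot sizes (20–1,000 px) and objective magnifications (100×…4×), and
  alignment *accuracy* — mean error
  `E‖(U,V)‖ ≈ 0.38 px` rounding floor plus degradation, landing at
  **≈ 0.4 px ≈ 80 nm** at a diffraction-limited 200 nm sampling.

Everything runs from plain TIFF/PNG rasters (codecs built in — no
external image libraries needed) and is seed-reproducible end to end.

## Worked example

Simulate a micro-patterned field, measure its islands, then recover a
planted rotation + shift between the "electron" and "light" views:

```r
library(clemalign)

gen <- generate_dot_matrix(dot_matrix_spec(512, 512, c(12, 18, 26, 40),
                                           target_coverage = 0.12, seed = 7))
round(gen$coverage, 4)
#> [1] 0.1158                      # measured foreground fraction

islands <- label_islands(gen$image, min_area_px = 20)
head(islands, 3)
#>   label pixel_count area_um2 perimeter_px circularity centroid_x centroid_y
#> 1     1        2075 8.766875      205.233   0.6190612   380.7060  217.59084
#> 2     2        1263 5.336175      123.135   1.0000000   428.6318   26.61124
#> 3     3        1258 5.315050      122.763   1.0000000   271.5994  242.24960
```

Labels are sorted by decreasing area; `area_um2` uses the 65 nm/px
matrix sampling; circularity 1 would be a perfect disk (large islands
formed by merged dots score lower). Now plant a 23° rotation and a
(30, −12) px shift and ask the ALIGN sweep to find it:

```r
em_mask <- gen$image$pixels > 0
bf_view <- fuse_channels(em_mask + 0, matrix(0, 512, 512),
                         invert_similarity(
                           similarity_transform(1, 23, c(30, -12))))[, , 1] > 0.5

rotational_align(em_mask, bf_view)
#> <AlignmentResult> theta = 23.00 deg, shift = (30, -12), score 0.6304
```

The angle is exact to the 0.1° refinement step and the shift to the
pixel; `score` is the normalised correlation peak in [0, 1]. The same
`AlignmentResult` feeds `fuse_channels()` to overlay real fluorescence
channels on the SEM frame.

A command-line front end mirrors the R API
(`segment`, `stitch`, `locate`, `align`, `fuse`, `simulate-matrix`,
`bench-efficiency`, `bench-accuracy`), e.g.:

```sh
Rscript inst/exec/clemalign align bf_mask.tif bs_mask.tif \
    --out result.json --profile profile.csv
```

## Acceptance benchmark

`scripts/acceptance.R` recomputes the headline accuracy number from
scratch — 10,000² mixed-dot matrix, 112 tile pairs (16 base crops × 7
random scale factors in (1, 4)), per-pair varied shifts, degradation
(downscale 3.846, 1% impulse noise, Gaussian blur σ = 1, threshold 100),
integer-pixel phase correlation — and writes the mean total deviation
`√(x² + y²)` in pixels of the diffraction-limited sampling:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
# [acceptance] mean deviation 0.3646 px (SEM 0.0146, 0/112 failed)
```

The published reference value for this protocol is 0.396 ± 0.02 px; the
irreducible floor for an integer-grid estimator on continuously shifted
content is `E√(U²+V²) = 0.3826` px, so seed-to-seed means land in the
0.36–0.39 range.

Runs in ~2 minutes on one CPU. The methods vignette
(`vignettes/micro-pattern-registration.Rmd`) documents the model, every
tunable default, what the synthetic generator does and does not emulate,
and the package's numerical conventions.
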