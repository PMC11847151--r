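# Process stage: resampling, windowing, rasterization, dose alignment.

test_that("rasterizer equals the brute-force even-odd oracle on random polygons", {
  set.seed(1234)
  mismatches <- 0L
  for (rep in 1:60) {
    nx <- sample(8:24, 1); ny <- sample(8:24, 1)
    nv <- sample(3:10, 1)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    cx <- stats::runif(1, 2, nx - 2); cy <- stats::runif(1, 2, ny - 2)
    r <- stats::runif(1, 0.5, min(nx, ny) / 2)
    px <- cx + r * cos(ang); py <- cy + r * sin(ang)
    got <- rtcurate:::.fill_polygon(px, py, nx, ny)
    want <- pip_oracle_mask(px, py, nx, ny)
    mismatches <- mismatches + sum(got != want)
  }
  expect_identical(mismatches, 0L)
})

test_that("an axis-aligned 10x10 mm square covers exactly 100 voxel centers", {
  # square with corners on the integer lattice; voxel centers at integer mm
  sq <- rtcurate:::.fill_polygon(c(11, 21, 21, 11), c(11, 11, 21, 21), 40, 40)
  expect_identical(sum(sq), 100L)
  # a center exactly on the left/bottom edge is inside, right/top outside
  expect_true(sq[12, 12] && sq[12, 21] && !sq[22, 12] && !sq[12, 22])
})

test_that("inner contours on one slice create holes (even-odd combination)", {
  # one ROI with two concentric squares on the same slice: a frame
  ref <- image_volume(array(0, c(30, 30, 1)), c(0, 0, 0), c(1, 1, 1))
  ring <- list(rois = list(list(
    name = "ring", number = 1L,
    contours = list(
      cbind(c(5, 25, 25, 5), c(5, 5, 25, 25), 0),
      cbind(c(10, 20, 20, 10), c(10, 10, 20, 20), 0)),
    flag_empty = FALSE)), referenced_series_uid = NA)
  class(ring) <- "structure_set"
  mask <- rasterize(ring, ref, processing_params(roi_patterns = list(ring = "ring")))
  expect_identical(sum(mask$voxels == 1), 400L - 100L)
  expect_identical(mask$voxels[16, 16, 1], 0L) # hole interior
  expect_identical(mask$voxels[8, 16, 1], 1L)  # frame
})

test_that("sphere mask volume and centroid match the analytic ground truth", {
  m <- fx_full_chain()
  gt <- m$ground_truth
  vol <- read_image_series(file.path(m$root, m$patients$P001$ct_files))
  ss <- read_rtstruct(file.path(m$root, m$patients$P001$rtstruct_file))
  mask <- rasterize(ss, vol, processing_params(roi_patterns = list(gtv = "GTV")))
  vox_vol <- sum(mask$voxels == 1) * prod(vol$spacing)
  expect_lt(abs(vox_vol - gt$analytic_volume_mm3) / gt$analytic_volume_mm3, 0.05)
  idx <- which(mask$voxels == 1, arr.ind = TRUE) - 1
  centroid <- rtcurate:::vox_to_phys(vol, colMeans(idx))
  expect_true(all(abs(centroid - gt$center_mm) < vol$spacing))
})

test_that("roi pattern matching is ordered, case-insensitive, full-string", {
  m <- fx_full_chain()
  vol <- read_image_series(file.path(m$root, m$patients$P001$ct_files))
  ss <- read_rtstruct(file.path(m$root, m$patients$P001$rtstruct_file))
  # case-insensitive full-string match
  mask <- rasterize(ss, vol, processing_params(roi_patterns = list(tumour = "gtv")))
  expect_gt(sum(mask$voxels == 1), 0L)
  # substring without anchors-matching pattern does not match partially
  mask0 <- rasterize(ss, vol,
                     processing_params(roi_patterns = list(tumour = "GT"),
                                       roi_missing_policy = "skip"))
  expect_identical(sum(mask0$voxels), 0L)
  # missing-policy behaviours
  pp_warn <- processing_params(roi_patterns = list(x = "nope"),
                               roi_missing_policy = "warn")
  expect_warning(rasterize(ss, vol, pp_warn), "matched no ROI")
  pp_err <- processing_params(roi_patterns = list(x = "nope"),
                              roi_missing_policy = "error")
  expect_error(rasterize(ss, vol, pp_err), "matched no ROI")
})

test_that("resampling follows the ceil(size * spacing / target) contract", {
  vol <- image_volume(array(stats::rnorm(64^3), c(64, 64, 64)),
                      c(0, 0, 0), c(1, 1, 1))
  out <- resample(vol, 2)
  expect_identical(dim(out$voxels), c(32L, 32L, 32L))
  expect_equal(out$origin, vol$origin)
  # identity resample is voxel-identical
  expect_identical(resample(vol, 1)$voxels, vol$voxels)
  # constant volume stays constant under any interpolator
  cv <- image_volume(array(7, c(10, 12, 8)), c(0, 0, 0), c(1, 1, 1))
  for (itp in c("linear", "nearest", "cubic"))
    expect_lt(max(abs(resample(cv, c(0.7, 1.3, 2), itp)$voxels - 7)), 1e-9)
})

test_that("linear fields survive down-and-back resampling within 1e-6", {
  n <- 24L
  xs <- array(rep(0:(n - 1L), times = n * n), c(n, n, n))
  vol <- image_volume(5 + 0.25 * xs, c(0, 0, 0), c(1, 1, 1))
  half <- resample(vol, 0.5, "linear")
  back <- resample(half, 1, "linear")
  expect_identical(dim(back$voxels), dim(vol$voxels))
  expect_lt(max(abs(back$voxels - vol$voxels) / abs(vol$voxels)), 1e-6)
})

test_that("windowing clips to [level - w/2, level + w/2] and is idempotent", {
  vol <- image_volume(array(seq(-2000, 2000, length.out = 4^3), c(4, 4, 4)),
                      c(0, 0, 0), c(1, 1, 1))
  w <- window_intensity(vol, 400, 40)
  expect_equal(range(w$voxels), c(-160, 240))
  expect_identical(window_intensity(w, 400, 40)$voxels, w$voxels)
  # window covering the whole data range is the identity
  wide <- window_intensity(vol, 1e6, 0)
  expect_identical(wide$voxels, vol$voxels)
  expect_error(window_intensity(vol, -5, 0), "width")
})

test_that("mask and image stay co-registered through joint resampling", {
  m <- fx_full_chain()
  gt <- m$ground_truth
  vol <- read_image_series(file.path(m$root, m$patients$P001$ct_files))
  ss <- read_rtstruct(file.path(m$root, m$patients$P001$rtstruct_file))
  res <- resample(vol, 2)
  mask <- rasterize(ss, res, processing_params(roi_patterns = list(gtv = "GTV")))
  idx <- which(mask$voxels == 1, arr.ind = TRUE) - 1
  centroid <- rtcurate:::vox_to_phys(res, colMeans(idx))
  expect_true(all(abs(centroid - gt$center_mm) < res$spacing))
})

test_that("dose alignment reproduces identity, constant and linear fields", {
  m <- fx_full_chain()
  p <- m$patients$P001
  dg <- read_rtdose(file.path(m$root, p$rtdose_file))
  # identity: aligning onto its own geometry changes nothing
  self <- align_dose(dg, dg)
  expect_equal(self$voxels, dg$voxels, tolerance = 1e-12)
  # constant field: constant inside the dose extent
  const <- dose_grid(array(2, dim(dg$voxels)), dg$origin, dg$spacing,
                     dg$direction)
  vol <- read_image_series(file.path(m$root, p$ct_files))
  ac <- align_dose(const, vol)
  expect_true(all(ac$voxels == 2))
  # linear gradient along x: matches the analytic field at voxel centers
  al <- align_dose(dg, vol)
  expected <- p$dose$base_gy + p$dose$gradient_x_gy_per_mm * (0:63)
  for (j in c(1, 32, 64)) for (k in c(1, 24, 48))
    expect_lt(max(abs(al$voxels[, j, k] - expected) / expected), 1e-6)
})

test_that("disjoint dose and image extents warn and return zero dose", {
  dg <- dose_grid(array(1, c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1))
  far <- image_volume(array(0, c(4, 4, 4)), c(1000, 1000, 1000), c(1, 1, 1))
  expect_warning(out <- align_dose(dg, far), "disjoint")
  expect_true(all(out$voxels == 0))
  # mismatched frame of reference UIDs are refused outright
  a <- dose_grid(array(1, c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1),
                 frame_of_reference_uid = "1.2.3")
  b <- image_volume(array(0, c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1),
                    frame_of_reference_uid = "4.5.6")
  expect_error(align_dose(a, b), "frame of reference")
})
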