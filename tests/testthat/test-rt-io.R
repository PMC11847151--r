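# rt_io: image series assembly, structure sets, dose grids, volume export.

test_that("slices are assembled by spatial position regardless of file order", {
  m <- fx_full_chain()
  p <- m$patients$P001
  files <- file.path(m$root, p$ct_files)
  set.seed(99)
  vol <- read_image_series(sample(files))
  expect_identical(dim(vol$voxels), c(64L, 64L, 48L))
  expect_equal(vol$spacing, c(1, 1, 1))
  expect_equal(vol$origin, c(0, 0, 0))
  expect_equal(vol$direction, diag(3))
  expect_identical(vol$intensity_units, "HU")
  # rescale slope/intercept applied: exact fixture HU values
  expect_setequal(unique(as.vector(vol$voxels)), c(-1000, 100))
  # voxel at the sphere center is soft tissue, corner is air
  expect_identical(vol$voxels[33, 33, 25], 100)
  expect_identical(vol$voxels[1, 1, 1], -1000)
})

test_that("degenerate and broken stacks are handled explicitly", {
  m <- fx_full_chain()
  p <- m$patients$P001
  files <- file.path(m$root, p$ct_files)
  single <- read_image_series(files[1])
  expect_identical(dim(single$voxels)[3], 1L)
  # removing a mid-stack slice must raise the non-uniform spacing error
  expect_error(read_image_series(files[-25]), "non-uniform")
  expect_warning(read_image_series(files[-25], allow_irregular = TRUE),
                 "non-uniform")
  # mixing series is refused
  q <- m$patients$P002
  expect_error(read_image_series(c(files[1], file.path(m$root, q$ct_files[1]))),
               "multiple series")
})

test_that("structure sets keep names verbatim and coordinates as stored", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(
    fixture_spec(n_patients = 1L, slices_per_series = 8L, rows = 24L,
                 cols = 24L, shape = "cuboid", shape_size = c(10, 10, 4),
                 roi_names = c("GTV  1", "ptv_total"), seed = 17L),
    file.path(dir, "names"))
  ss <- read_rtstruct(file.path(m$root, m$patients$P001$rtstruct_file))
  expect_identical(vapply(ss$rois, `[[`, "", "name"), c("GTV  1", "ptv_total"))
  expect_identical(ss$referenced_series_uid, m$patients$P001$ct_series_uid)
  # cuboid contour: 4 corners at exactly the written coordinates
  ctr <- ss$rois[[1]]$contours[[1]]
  expect_identical(nrow(ctr), 4L)
  expect_setequal(ctr[, 1], c(7, 17)) # center x = 12, half-width 5
  expect_setequal(ctr[, 2], c(7, 17))
  # every contour is planar (constant z)
  for (ct in ss$rois[[1]]$contours) expect_identical(length(unique(ct[, 3])), 1L)
})

test_that("sphere contours match the analytic circle radius per slice", {
  m <- fx_full_chain()
  ss <- read_rtstruct(file.path(m$root, m$patients$P001$rtstruct_file))
  gt <- m$ground_truth
  expect_length(ss$rois[[1]]$contours, 39L) # slices within |z - 24| < 20
  for (ct in ss$rois[[1]]$contours[c(1, 20, 39)]) {
    z <- ct[1, 3]
    rz <- sqrt(gt$shape_size^2 - (z - gt$center_mm[3])^2)
    radii <- sqrt((ct[, 1] - gt$center_mm[1])^2 + (ct[, 2] - gt$center_mm[2])^2)
    expect_lt(max(abs(radii - rz)), 1e-3) # 4-decimal rounding only
  }
})

test_that("dose grids are scaled to Gy and never assume a missing factor", {
  m <- fx_full_chain()
  p <- m$patients$P001
  dg <- read_rtdose(file.path(m$root, p$rtdose_file))
  expect_true(dg$scaling_applied)
  expect_equal(max(dg$voxels), 50) # stored 5000 x scaling 0.01
  expect_equal(dg$spacing, c(2, 2, 2)) # from offsets [0, 2, 4, ...]
  expect_equal(dg$origin, c(0, 0, 0))
  # dose linearity: doubling the scaling factor doubles every Gy value
  dir <- withr::local_tempdir()
  m2 <- generate_dataset(
    fixture_spec(n_patients = 1L, slices_per_series = 6L, rows = 16L,
                 cols = 16L, shape_size = 3, dose_scaling = 0.02,
                 include_rtplan = TRUE, include_rtdose = TRUE, seed = 19L),
    file.path(dir, "d2"))
  m1 <- generate_dataset(
    fixture_spec(n_patients = 1L, slices_per_series = 6L, rows = 16L,
                 cols = 16L, shape_size = 3, dose_scaling = 0.01,
                 include_rtplan = TRUE, include_rtdose = TRUE, seed = 19L),
    file.path(dir, "d1"))
  g2 <- read_rtdose(file.path(m2$root, m2$patients$P001$rtdose_file))
  g1 <- read_rtdose(file.path(m1$root, m1$patients$P001$rtdose_file))
  expect_equal(max(g2$voxels), 100)
  expect_equal(max(g2$voxels) / max(g1$voxels), 2)
  # a dose file with the scaling element spliced out must error
  broken <- file.path(dir, "broken.dcm")
  file.copy(file.path(m$root, p$rtdose_file), broken)
  rtcurate:::dcm_strip_tag(broken, "DoseGridScaling")
  expect_error(read_rtdose(broken), "DoseGridScaling")
})

test_that("NIfTI and NRRD round trips preserve voxels and geometry", {
  m <- fx_full_chain()
  vol <- read_image_series(file.path(m$root, m$patients$P001$ct_files))
  dir <- withr::local_tempdir()
  for (case in list(c("nifti", "v.nii.gz"), c("nrrd", "v.nrrd"))) {
    path <- file.path(dir, case[2])
    write_volume(vol, path, case[1])
    back <- read_volume(path)
    expect_identical(back$voxels, vol$voxels)
    expect_lt(max(abs(back$origin - vol$origin)), 1e-3)
    expect_lt(max(abs(back$spacing - vol$spacing)), 1e-6)
    expect_lt(max(abs(back$direction - vol$direction)), 1e-6)
  }
  expect_error(write_volume(vol, file.path(dir, "x.nrrd"), "nifti"), "nii")
  expect_error(write_volume(vol, file.path(dir, "x.nii.gz"), "nrrd"), "nrrd")
})

test_that("exported volumes carry correct LPS geometry for external readers", {
  # SimpleITK (independent implementation) must see the same physical
  # geometry we wrote, for both formats
  dir <- withr::local_tempdir()
  vol <- image_volume(array(as.double(1:60), c(3, 4, 5)),
                      origin = c(-7.5, 12.25, 3), spacing = c(0.5, 0.75, 2),
                      modality = "CT", intensity_units = "HU")
  write_volume(vol, file.path(dir, "g.nii.gz"), "nifti")
  write_volume(vol, file.path(dir, "g.nrrd"), "nrrd")
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, SimpleITK as sitk",
    "for f in sys.argv[1:]:",
    "    im = sitk.ReadImage(f)",
    "    assert max(abs(a-b) for a,b in zip(im.GetOrigin(), (-7.5,12.25,3))) < 1e-3, f",
    "    assert max(abs(a-b) for a,b in zip(im.GetSpacing(), (0.5,0.75,2))) < 1e-6, f",
    "    assert im.GetSize() == (3,4,5), f",
    "print('ok')"), script)
  out <- system2("python", c(script, file.path(dir, "g.nii.gz"),
                             file.path(dir, "g.nrrd")),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(tail(out, 1), "ok")
})
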