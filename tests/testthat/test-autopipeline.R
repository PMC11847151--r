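# End-to-end orchestration: determinism, pre-crawl equivalence, crash
# containment, nnU-Net export, CLI.

pp_gtv <- function() processing_params(roi_patterns = list(gtv = "GTV"))

run_quiet <- function(cfg) suppressMessages(run_pipeline(cfg))

test_that("one command turns the fixture into per-sample image+mask+dose trees", {
  m <- fx_full_chain()
  out <- file.path(withr::local_tempdir(), "out")
  cfg <- pipeline_config(m$root, out, modalities = "CT,RTSTRUCT,RTDOSE",
                         processing = pp_gtv())
  manifest <- run_quiet(cfg)
  expect_identical(nrow(manifest), 2L)
  expect_true(all(manifest$status == "ok"))
  expect_identical(attr(manifest, "n_failed"), 0L)
  for (i in 1:2) {
    paths <- strsplit(manifest$outputs[i], ";")[[1]]
    expect_setequal(basename(paths),
                    c("CT.nii.gz", "RTDOSE.nii.gz", "mask_gtv.nii.gz"))
    expect_true(all(file.exists(file.path(out, paths))))
  }
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "run_info.json")))
  # the index and run artifacts live under .imgtools at the input root
  expect_true(file.exists(file.path(m$root, ".imgtools", "series.csv")))
  expect_true(file.exists(file.path(m$root, ".imgtools", "unmatched.csv")))
  # mask voxel count recovers the sphere volume on the processed output
  mask <- read_volume(file.path(out, grep("mask", strsplit(
    manifest$outputs[1], ";")[[1]], value = TRUE)))
  vol_mm3 <- sum(mask$voxels == 1) * prod(mask$spacing)
  expect_lt(abs(vol_mm3 - m$ground_truth$analytic_volume_mm3) /
              m$ground_truth$analytic_volume_mm3, 0.05)
})

test_that("outputs are byte-identical across worker counts", {
  m <- fx_full_chain()
  base <- withr::local_tempdir()
  cfg1 <- pipeline_config(m$root, file.path(base, "w1"),
                          modalities = "CT,RTSTRUCT,RTDOSE",
                          processing = pp_gtv(), n_workers = 1L)
  cfg4 <- pipeline_config(m$root, file.path(base, "w4"),
                          modalities = "CT,RTSTRUCT,RTDOSE",
                          processing = pp_gtv(), n_workers = 4L)
  run_quiet(cfg1); run_quiet(cfg4)
  expect_identical_trees(file.path(base, "w1"), file.path(base, "w4"))
})

test_that("a pre-crawled index reproduces the crawl path byte for byte", {
  m <- fx_full_chain()
  base <- withr::local_tempdir()
  cfg <- pipeline_config(m$root, file.path(base, "crawl"),
                         modalities = "CT,RTSTRUCT", processing = pp_gtv())
  run_quiet(cfg) # also saves the index under <input>/.imgtools
  cfg2 <- pipeline_config(m$root, file.path(base, "preloaded"),
                          modalities = "CT,RTSTRUCT", processing = pp_gtv(),
                          preloaded_index = file.path(m$root, ".imgtools"))
  run_quiet(cfg2)
  expect_identical_trees(file.path(base, "crawl"), file.path(base, "preloaded"))
})

test_that("one corrupted sample fails alone; the rest is unaffected", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_patients = 2L, slices_per_series = 8L, rows = 20L,
                       cols = 20L, shape_size = 4, seed = 53L)
  m_clean <- generate_dataset(spec, file.path(dir, "clean"))
  m_bad <- generate_dataset(spec, file.path(dir, "bad"))
  # truncate one CT slice of P002 after the crawl would still parse it:
  # chop the tail so pixel reading fails at process time
  victim <- file.path(m_bad$root, m_bad$patients$P002$ct_files[4])
  bytes <- readBin(victim, "raw", n = file.size(victim))
  writeBin(bytes[1:(length(bytes) - 500L)], victim)
  out_clean <- file.path(dir, "out_clean"); out_bad <- file.path(dir, "out_bad")
  run_quiet(pipeline_config(m_clean$root, out_clean, processing = pp_gtv()))
  mb <- run_quiet(pipeline_config(m_bad$root, out_bad, processing = pp_gtv()))
  expect_identical(attr(mb, "n_failed"), 1L)
  expect_identical(mb$status[mb$patient_id == "P002"], "failed")
  expect_match(mb$reason[mb$patient_id == "P002"], ".+")
  # P001's outputs are byte-identical to the clean run's
  p1 <- list.files(file.path(out_clean, "P001"), recursive = TRUE)
  expect_identical(list.files(file.path(out_bad, "P001"), recursive = TRUE), p1)
  for (f in p1)
    expect_identical(
      readBin(file.path(out_bad, "P001", f), "raw",
              file.size(file.path(out_bad, "P001", f))),
      readBin(file.path(out_clean, "P001", f), "raw",
              file.size(file.path(out_clean, "P001", f))))
})

test_that("zero matching samples abort with a pointer to the unmatched report", {
  m <- fx_small()
  out <- file.path(withr::local_tempdir(), "out")
  cfg <- pipeline_config(m$root, out, modalities = "MR")
  expect_error(run_quiet(cfg), "unmatched")
})

test_that("overwrite policies guard existing sample outputs", {
  m <- fx_small()
  base <- withr::local_tempdir()
  out <- file.path(base, "out")
  cfg <- pipeline_config(m$root, out, processing = pp_gtv())
  run_quiet(cfg)
  expect_error(run_quiet(cfg), "collision")
  cfg_skip <- pipeline_config(m$root, out, processing = pp_gtv(),
                              overwrite_policy = "skip_existing")
  sample_file <- list.files(out, pattern = "CT.nii.gz", recursive = TRUE,
                            full.names = TRUE)[1]
  before <- file.mtime(sample_file)
  Sys.sleep(1.1)
  mskip <- run_quiet(cfg_skip)
  expect_true(all(mskip$status == "ok"))
  expect_identical(file.mtime(sample_file), before) # nothing rewritten
  cfg_ow <- pipeline_config(m$root, out, processing = pp_gtv(),
                            overwrite_policy = "overwrite")
  expect_silent(suppressMessages(run_pipeline(cfg_ow)))
})

test_that("nnU-Net export writes the documented layout with correct counts", {
  m <- fx_full_chain()
  out <- file.path(withr::local_tempdir(), "out")
  cfg <- pipeline_config(m$root, out, modalities = "CT,RTSTRUCT",
                         processing = pp_gtv(), nnunet = TRUE,
                         nnunet_task = "SPHERE")
  run_quiet(cfg)
  img <- list.files(file.path(out, "nnunet", "imagesTr"))
  lab <- list.files(file.path(out, "nnunet", "labelsTr"))
  expect_identical(img, c("SPHERE_0001_0000.nii.gz", "SPHERE_0002_0000.nii.gz"))
  expect_identical(lab, c("SPHERE_0001.nii.gz", "SPHERE_0002.nii.gz"))
  dj <- jsonlite::read_json(file.path(out, "nnunet", "dataset.json"))
  expect_identical(dj$numTraining, 2L)
  expect_identical(dj$labels[["0"]], "background")
  expect_identical(dj$labels[["1"]], "gtv")
  expect_length(dj$labels, 2L)
  # label volume equals the standard-layout mask
  lv <- read_volume(file.path(out, "nnunet", "labelsTr", lab[1]))
  expect_setequal(unique(as.vector(lv$voxels)), c(0, 1))
  # an empty label map is refused before anything is written
  expect_error(export_nnunet(out, "T", character(0)), "empty label map")
  # re-export with skip_existing rewrites nothing
  f <- file.path(out, "nnunet", "imagesTr", img[1])
  before <- file.mtime(f)
  Sys.sleep(1.1)
  export_nnunet(out, "SPHERE", "gtv", overwrite_policy = "skip_existing")
  expect_identical(file.mtime(f), before)
})

test_that("the command-line wrapper runs end to end with exit code 0", {
  m <- fx_small()
  out <- file.path(withr::local_tempdir(), "cli_out")
  cli <- system.file("cli", "autopipeline.R", package = "rtcurate")
  expect_true(nzchar(cli))
  res <- suppressWarnings(system2("Rscript", c(cli, m$root, out),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0L)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  mf <- utils::read.csv(file.path(out, "manifest.csv"))
  expect_identical(nrow(mf), 2L)
})

test_that("YAML config files round into pipeline settings with CLI precedence", {
  dir <- withr::local_tempdir()
  cfg_file <- file.path(dir, "cfg.yaml")
  writeLines(c("modalities: CT,RTSTRUCT",
               "spacing: [2, 2, 2]",
               "window: [400, 40]",
               "roi_patterns:",
               "  gtv:",
               "    - GTV.*"), cfg_file)
  s <- read_pipeline_config(cfg_file)
  expect_identical(s$modalities, "CT,RTSTRUCT")
  expect_equal(unlist(s$spacing), c(2, 2, 2))
  cfg <- rtcurate:::.pipeline_config_from_settings("in", "out", s)
  expect_equal(cfg$processing$target_spacing, c(2, 2, 2))
  expect_equal(cfg$processing$window, c(400, 40))
  expect_identical(names(cfg$processing$roi_patterns), "gtv")
  writeLines("bogus_key: 1", cfg_file)
  expect_error(read_pipeline_config(cfg_file), "unknown config key")
})
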