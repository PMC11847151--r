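# Shared fixtures and independent oracles. Fixture datasets are generated
# once per test run (lazily, in tempdir) and reused across files; they are
# deterministic, so sharing cannot leak state between tests.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, spec) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("rtcurate_fx_", key))
  unlink(dir, recursive = TRUE)
  manifest <- generate_dataset(spec, dir)
  .fixture_cache[[key]] <- manifest
  manifest
}

# canonical 2-patient dataset: full RTDOSE -> RTPLAN -> RTSTRUCT -> CT
# chain, 20 mm sphere in a 64 x 64 x 48 CT at 1 mm spacing
fx_full_chain <- function() {
  cached_fixture("full", fixture_spec(n_patients = 2L, include_rtplan = TRUE,
                                      include_rtdose = TRUE, seed = 11L))
}

# small 2-patient CT + RTSTRUCT dataset (10 slices, 4 mm sphere)
fx_small <- function() {
  cached_fixture("small", fixture_spec(n_patients = 2L, slices_per_series = 10L,
                                       rows = 24L, cols = 24L,
                                       shape_size = 4, seed = 7L))
}

# brute-force even-odd point-in-polygon: the rasterization oracle. Tests
# every voxel center of an nx x ny grid independently against every edge
# (ray to +x from the point nudged by +1e-9 on both axes).
pip_oracle_mask <- function(px, py, nx, ny) {
  eps <- 1e-9
  n <- length(px)
  x2 <- px[c(2:n, 1L)]; y2 <- py[c(2:n, 1L)]
  m <- matrix(FALSE, nx, ny)
  for (j in 0:(ny - 1L)) {
    y <- j + eps
    for (i in 0:(nx - 1L)) {
      x <- i + eps
      cnt <- 0L
      for (e in seq_len(n)) {
        y1e <- py[e]; y2e <- y2[e]
        if ((y1e > y) != (y2e > y)) {
          xc <- px[e] + (y - y1e) * (x2[e] - px[e]) / (y2e - y1e)
          if (xc > x) cnt <- cnt + 1L
        }
      }
      m[i + 1L, j + 1L] <- cnt %% 2L == 1L
    }
  }
  m
}

# compare two directory trees byte for byte
expect_identical_trees <- function(a, b, exclude = character(0)) {
  fa <- setdiff(list.files(a, recursive = TRUE), exclude)
  fb <- setdiff(list.files(b, recursive = TRUE), exclude)
  expect_identical(fa, fb)
  for (f in fa) {
    ba <- readBin(file.path(a, f), "raw", n = file.size(file.path(a, f)))
    bb <- readBin(file.path(b, f), "raw", n = file.size(file.path(b, f)))
    if (!identical(ba, bb)) {
      fail(paste0("tree mismatch at ", f))
      return(invisible(FALSE))
    }
  }
  succeed()
  invisible(TRUE)
}
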