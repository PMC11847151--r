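# Stage 3, "process": the per-sample image transformations. Geometry flows
# through the voxel<->physical mapping in geometry.R; interpolation,
# contour rasterization and dose alignment all operate in that frame.

#' Processing parameters for the pipeline
#'
#' @param target_spacing mm triple to resample to, or `NULL` for no
#'   resampling.
#' @param window optional `c(width, level)` in HU; voxels are clipped to
#'   `[level - width/2, level + width/2]`.
#' @param roi_patterns ordered named list: output label name -> character
#'   vector of case-insensitive, full-string regular expressions matched
#'   against ROI names. `NULL` means every ROI becomes its own label.
#' @param roi_missing_policy what to do when a pattern matches no ROI:
#'   `"skip"` (silent), `"warn"` or `"error"`.
#' @param image_interp interpolator for images and dose: `"linear"`,
#'   `"nearest"` or `"cubic"` (separable Catmull-Rom convolution; the
#'   common smooth alternative, also accepted under the alias
#'   `"bspline"`). Masks always use nearest neighbour.
#' @return a `processing_params` object.
#' @export
processing_params <- function(target_spacing = NULL, window = NULL,
                              roi_patterns = NULL,
                              roi_missing_policy = c("warn", "skip", "error"),
                              image_interp = c("linear", "nearest", "cubic",
                                               "bspline")) {
  roi_missing_policy <- match.arg(roi_missing_policy)
  image_interp <- match.arg(image_interp)
  if (image_interp == "bspline") image_interp <- "cubic"
  if (!is.null(target_spacing)) {
    target_spacing <- as.numeric(target_spacing)
    if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
    if (length(target_spacing) != 3L || any(target_spacing <= 0))
      stop("target_spacing must be a strictly positive mm triple")
  }
  if (!is.null(window)) {
    window <- as.numeric(window)
    if (length(window) != 2L || window[1] <= 0)
      stop("window must be c(width, level) with width > 0")
  }
  if (!is.null(roi_patterns)) {
    if (is.character(roi_patterns))
      roi_patterns <- stats::setNames(as.list(roi_patterns),
                                      names(roi_patterns) %||% roi_patterns)
    if (is.null(names(roi_patterns)) || any(!nzchar(names(roi_patterns))))
      stop("roi_patterns must be a named list (output name -> regexes)")
  }
  structure(list(target_spacing = target_spacing, window = window,
                 roi_patterns = roi_patterns,
                 roi_missing_policy = roi_missing_policy,
                 image_interp = image_interp, mask_interp = "nearest"),
            class = "processing_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interpolate vol at physical points (n x 3 mm), returning a value per
# point. outside = "nearest" clamps to the border (used when resampling a
# volume onto a grid covering its own extent); "zero" returns `fill`
# outside the volume (used for dose alignment).
.interp_at <- function(vol, pts, interp = "linear", outside = "nearest",
                       fill = 0) {
  idx <- phys_to_vox(vol, pts) # continuous 0-based
  d <- dim(vol$voxels)
  out_of_grid <- idx[, 1] < -0.5 | idx[, 1] > d[1] - 0.5 |
                 idx[, 2] < -0.5 | idx[, 2] > d[2] - 0.5 |
                 idx[, 3] < -0.5 | idx[, 3] > d[3] - 0.5
  clamp <- function(v, n) pmin(pmax(v, 0L), n - 1L)
  lin <- function(i, j, k) 1L + i + d[1] * (j + d[2] * k)
  vals <- if (interp == "nearest") {
    vol$voxels[lin(clamp(round(idx[, 1]), d[1]), clamp(round(idx[, 2]), d[2]),
                   clamp(round(idx[, 3]), d[3]))]
  } else if (interp == "linear") {
    i0 <- floor(idx)
    fr <- idx - i0
    acc <- numeric(nrow(idx))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) fr[, 1] else 1 - fr[, 1]) *
           (if (dj) fr[, 2] else 1 - fr[, 2]) *
           (if (dk) fr[, 3] else 1 - fr[, 3])
      acc <- acc + w * vol$voxels[lin(clamp(i0[, 1] + di, d[1]),
                                      clamp(i0[, 2] + dj, d[2]),
                                      clamp(i0[, 3] + dk, d[3]))]
    }
    acc
  } else if (interp == "cubic") {
    # separable Catmull-Rom cubic convolution (a = -0.5)
    cr <- function(t) { # weights for taps at offsets -1..2, t in [0,1)
      t2 <- t * t; t3 <- t2 * t
      cbind(-0.5 * t3 + t2 - 0.5 * t,
            1.5 * t3 - 2.5 * t2 + 1,
            -1.5 * t3 + 2 * t2 + 0.5 * t,
            0.5 * t3 - 0.5 * t2)
    }
    i0 <- floor(idx)
    wx <- cr(idx[, 1] - i0[, 1]); wy <- cr(idx[, 2] - i0[, 2])
    wz <- cr(idx[, 3] - i0[, 3])
    acc <- numeric(nrow(idx))
    for (di in -1:2) for (dj in -1:2) for (dk in -1:2) {
      w <- wx[, di + 2L] * wy[, dj + 2L] * wz[, dk + 2L]
      acc <- acc + w * vol$voxels[lin(clamp(i0[, 1] + di, d[1]),
                                      clamp(i0[, 2] + dj, d[2]),
                                      clamp(i0[, 3] + dk, d[3]))]
    }
    acc
  } else stop("unknown interpolator: ", interp)
  if (outside == "zero") vals[out_of_grid] <- fill
  vals
}

#' Resample a volume to a new spacing
#'
#' The output grid keeps the input origin and direction and covers the full
#' input physical extent: size per axis is
#' `ceiling(input_size * input_spacing / target_spacing)`. Values are
#' interpolated at the new voxel centers (border-clamped).
#'
#' @param vol an [image_volume()].
#' @param target_spacing mm triple (or scalar, applied to all axes).
#' @param interp `"linear"`, `"nearest"` or `"cubic"`.
#' @return the resampled [image_volume()].
#' @export
resample <- function(vol, target_spacing, interp = "linear") {
  if (interp == "bspline") interp <- "cubic"
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  d <- dim(vol$voxels)
  nd <- as.integer(ceiling(d * vol$spacing / target_spacing))
  if (identical(nd, d) && all(target_spacing == vol$spacing)) return(vol)
  out <- vol
  out$spacing <- target_spacing
  grid <- as.matrix(expand.grid(i = 0:(nd[1] - 1L), j = 0:(nd[2] - 1L),
                                k = 0:(nd[3] - 1L)))
  tmp <- image_volume(array(0, nd), vol$origin, target_spacing, vol$direction)
  pts <- vox_to_phys(tmp, grid)
  out$voxels <- array(.interp_at(vol, pts, interp, outside = "nearest"), nd)
  out
}

#' Clip intensities to a Hounsfield window
#'
#' @param vol an [image_volume()].
#' @param width window width in HU (> 0).
#' @param level window level (center) in HU.
#' @return the volume with voxels clipped to
#'   `[level - width/2, level + width/2]`; geometry unchanged.
#' @export
window_intensity <- function(vol, width, level) {
  if (width <= 0) stop("window width must be > 0")
  vol$voxels[] <- pmin(pmax(vol$voxels, level - width / 2), level + width / 2)
  vol
}

# Even-odd scanline fill of one planar polygon over the integer lattice
# (voxel centers) of an nx x ny grid; polygon vertices in continuous
# 0-based index coordinates. A center lying exactly on an edge is resolved
# by nudging the test point by +1e-9 along both axes.
.fill_polygon <- function(px, py, nx, ny) {
  eps <- 1e-9
  m <- matrix(FALSE, nx, ny)
  n <- length(px)
  x1 <- px; y1 <- py
  x2 <- px[c(2:n, 1L)]; y2 <- py[c(2:n, 1L)]
  jmin <- max(0L, ceiling(min(py) - eps))
  jmax <- min(ny - 1L, floor(max(py) + eps))
  if (jmax < jmin) return(m)
  for (j in jmin:jmax) {
    yl <- j + eps
    cross <- (y1 > yl) != (y2 > yl)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (yl - y1[cross]) * (x2[cross] - x1[cross]) /
                 (y2[cross] - y1[cross]))
    centers <- 0:(nx - 1L) + eps
    inside <- (length(xs) - findInterval(centers, xs)) %% 2L == 1L
    m[, j + 1L] <- inside
  }
  m
}

.match_rois <- function(roi_names, patterns) {
  hits <- rep(FALSE, length(roi_names))
  for (pat in patterns) {
    re <- paste0("^(?:", pat, ")$")
    hits <- hits | grepl(re, roi_names, ignore.case = TRUE, perl = TRUE)
  }
  which(hits)
}

#' Rasterize a structure set onto a reference image grid
#'
#' Each requested output label is matched against the ROI names
#' (case-insensitive, full-string regular expressions, first pattern list
#' wins); the matched ROIs' planar contours are mapped from patient mm to
#' continuous voxel indices of the reference geometry, and each slice
#' polygon is filled by the even-odd rule over voxel centers. Multiple
#' contours on one slice combine by even-odd as well, so inner contours
#' create holes. Labels are assigned in `roi_patterns` order; a later
#' label overwrites earlier ones where they overlap.
#'
#' @param structs a `structure_set` from [read_rtstruct()].
#' @param reference the [image_volume()] defining the output grid.
#' @param params a [processing_params()]; uses `roi_patterns` and
#'   `roi_missing_policy`.
#' @return a [segmentation_mask()].
#' @export
rasterize <- function(structs, reference, params = processing_params()) {
  stopifnot(inherits(structs, "structure_set"),
            inherits(reference, "image_volume"))
  d <- dim(reference$voxels)
  roi_names <- vapply(structs$rois, `[[`, "", "name")
  patterns <- params$roi_patterns
  if (is.null(patterns))
    patterns <- stats::setNames(
      lapply(roi_names, function(nm) paste0("\\Q", nm, "\\E")), roi_names)
  labels <- array(0L, d)
  label_map <- integer(0)
  lab <- 0L
  for (out_name in names(patterns)) {
    lab <- lab + 1L
    label_map[out_name] <- lab
    ix <- .match_rois(roi_names, patterns[[out_name]])
    if (length(ix) == 0L) {
      msg <- paste0("roi_patterns['", out_name, "'] matched no ROI (have: ",
                    paste(roi_names, collapse = ", "), ")")
      switch(params$roi_missing_policy,
             error = stop(msg), warn = warning(msg), skip = NULL)
      next
    }
    if (length(ix) > 1L)
      message("label '", out_name, "' merges ", length(ix), " ROIs: ",
              paste(roi_names[ix], collapse = ", "))
    contours <- do.call(c, lapply(structs$rois[ix], `[[`, "contours"))
    if (length(contours) == 0L) next
    # group contour polygons by nearest slice of the reference grid
    by_slice <- list()
    for (poly in contours) {
      idx <- phys_to_vox(reference, poly)
      k <- round(mean(idx[, 3]))
      if (k < 0 || k >= d[3]) next
      key <- as.character(k)
      by_slice[[key]] <- c(by_slice[[key]], list(idx[, 1:2, drop = FALSE]))
    }
    for (key in names(by_slice)) {
      k <- as.integer(key)
      acc <- matrix(FALSE, d[1], d[2])
      for (poly2 in by_slice[[key]])
        acc <- xor(acc, .fill_polygon(poly2[, 1], poly2[, 2], d[1], d[2]))
      sl <- labels[, , k + 1L]
      sl[acc] <- lab
      labels[, , k + 1L] <- sl
    }
  }
  segmentation_mask(labels, reference, label_map)
}

#' Align a dose grid onto a reference image geometry
#'
#' Resamples the dose onto the reference grid (default linear
#' interpolation); reference voxels outside the dose extent are 0 Gy. When
#' both objects carry a frame of reference UID the pair is checked; when
#' the physical extents are disjoint the result is all zeros with a
#' warning rather than an error, so one bad sample cannot abort a bulk
#' run.
#'
#' @param dose a [dose_grid()].
#' @param reference the [image_volume()] to align onto.
#' @param interp `"linear"`, `"nearest"` or `"cubic"`.
#' @return a [dose_grid()] on the reference geometry.
#' @export
align_dose <- function(dose, reference, interp = "linear") {
  stopifnot(inherits(dose, "dose_grid"), inherits(reference, "image_volume"))
  if (interp == "bspline") interp <- "cubic"
  fu_d <- dose$frame_of_reference_uid; fu_r <- reference$frame_of_reference_uid
  if (!is.null(fu_d) && !is.null(fu_r) && !is.na(fu_d) && !is.na(fu_r) &&
      fu_d != fu_r)
    stop("dose and reference have different frame of reference UIDs: ",
         fu_d, " vs ", fu_r)
  d <- dim(reference$voxels)
  grid <- as.matrix(expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                                k = 0:(d[3] - 1L)))
  pts <- vox_to_phys(reference, grid)
  # disjoint extents: every reference corner outside the dose bounding box
  didx <- phys_to_vox(dose, pts)
  dd <- dim(dose$voxels)
  inside <- didx[, 1] >= -0.5 & didx[, 1] <= dd[1] - 0.5 &
            didx[, 2] >= -0.5 & didx[, 2] <= dd[2] - 0.5 &
            didx[, 3] >= -0.5 & didx[, 3] <= dd[3] - 0.5
  if (!any(inside)) {
    warning("dose grid and reference image have disjoint physical extents; ",
            "returning all-zero dose")
    vals <- numeric(nrow(pts))
  } else {
    vals <- .interp_at(dose, pts, interp, outside = "zero", fill = 0)
    vals <- pmax(vals, 0) # cubic convolution may undershoot slightly
  }
  out <- dose_grid(array(vals, d), reference$origin, reference$spacing,
                   reference$direction,
                   frame_of_reference_uid = reference$frame_of_reference_uid)
  out
}
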