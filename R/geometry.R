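# In-memory volume container and its geometry model.
#
# Convention used throughout the package: DICOM patient LPS coordinates,
# 0-based voxel indices, voxel array stored as (col, row, slice) = (x, y, z)
# so the first array index varies fastest, matching both DICOM PixelData
# byte order and the NIfTI on-disk layout. The physical position of voxel
# (i, j, k) is origin + direction %*% (spacing * c(i, j, k)); that equation
# is the single source of truth for all geometry in the package.

#' Construct an image volume
#'
#' A 3-D voxel grid with physical geometry in DICOM patient (LPS)
#' coordinates. Voxel array axes are (column, row, slice); the physical
#' position of 0-based voxel index \eqn{(i,j,k)} is
#' \eqn{origin + D (s \circ (i,j,k))} with direction matrix \eqn{D}
#' (columns are the axis direction cosines) and spacing \eqn{s} in mm.
#'
#' @param voxels 3-D numeric array, dimensions (columns, rows, slices).
#' @param origin length-3 numeric, mm position of voxel (0,0,0).
#' @param spacing length-3 positive numeric, mm per voxel along (x, y, z).
#' @param direction 3x3 orthonormal direction cosine matrix (columns = axes).
#' @param modality modality string, e.g. "CT".
#' @param intensity_units units of the voxel values ("HU" for CT, "Gy" for
#'   dose, "label" for masks).
#' @param frame_of_reference_uid optional DICOM frame of reference UID.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, origin, spacing,
                         direction = diag(3), modality = "unknown",
                         intensity_units = "arbitrary",
                         frame_of_reference_uid = NULL) {
  stopifnot(length(dim(voxels)) == 3L, length(origin) == 3L,
            length(spacing) == 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix is not orthonormal within 1e-6")
  structure(list(voxels = voxels, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), direction = direction,
                 modality = modality, intensity_units = intensity_units,
                 frame_of_reference_uid = frame_of_reference_uid),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels (%s)\n",
              x$modality, d[1], d[2], d[3], x$intensity_units))
  cat(sprintf("  origin  %s mm\n", paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  spacing %s mm\n", paste(signif(x$spacing, 6), collapse = ", ")))
  rng <- range(x$voxels)
  cat(sprintf("  range   [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# physical mm coordinates of 0-based voxel indices (n x 3 matrix)
vox_to_phys <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(idx %*% diag(vol$spacing) %*% t(vol$direction), 2L, vol$origin, "+")
}

# continuous 0-based voxel indices of physical mm points (n x 3 matrix)
phys_to_vox <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(pts, 2L, vol$origin, "-") %*% vol$direction %*% diag(1 / vol$spacing)
}

#' Construct a segmentation mask
#'
#' An integer label volume sharing the geometry of a reference image.
#' Label 0 is background; `label_map` names every nonzero label.
#'
#' @param labels 3-D integer array, same dimensions as the reference.
#' @param reference the `image_volume` whose geometry the mask shares.
#' @param label_map named integer vector mapping ROI output names to label
#'   values.
#' @return an object of classes `segmentation_mask` and `image_volume`.
#' @export
segmentation_mask <- function(labels, reference, label_map) {
  stopifnot(identical(dim(labels), dim(reference$voxels)))
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!all(present %in% label_map))
    stop("mask contains labels missing from label_map")
  vol <- image_volume(labels, reference$origin, reference$spacing,
                      reference$direction, modality = "SEG",
                      intensity_units = "label",
                      frame_of_reference_uid = reference$frame_of_reference_uid)
  vol$label_map <- label_map
  class(vol) <- c("segmentation_mask", class(vol))
  vol
}

#' Construct a dose grid
#'
#' An `image_volume` whose voxels are absorbed dose in Gy (the dose grid
#' scaling factor has already been applied).
#'
#' @param voxels,origin,spacing,direction,frame_of_reference_uid as in
#'   [image_volume()].
#' @return an object of classes `dose_grid` and `image_volume`.
#' @export
dose_grid <- function(voxels, origin, spacing, direction = diag(3),
                      frame_of_reference_uid = NULL) {
  if (any(voxels < 0)) stop("dose values must be non-negative")
  vol <- image_volume(voxels, origin, spacing, direction,
                      modality = "RTDOSE", intensity_units = "Gy",
                      frame_of_reference_uid = frame_of_reference_uid)
  vol$scaling_applied <- TRUE
  class(vol) <- c("dose_grid", class(vol))
  vol
}
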