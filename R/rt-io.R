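# Readers for the three DICOM-RT object families: image series (CT/MR/PT,
# one file per slice), RT Structure Sets (named planar contours in patient
# coordinates) and RT Dose grids (scaled stored integers -> Gy).

#' Read a DICOM image series into a volume
#'
#' Files may be listed in any order: slices are sorted by the projection of
#' their image position onto the slice normal (the cross product of the row
#' and column direction cosines). Slice spacing is inferred from the sorted
#' positions and must be uniform within a relative tolerance of 1e-3;
#' rescale slope and intercept are applied so CT voxels come out in
#' Hounsfield units.
#'
#' @param files paths of every slice of one series.
#' @param allow_irregular downgrade the non-uniform-spacing error to a
#'   warning (the mean gap is then used).
#' @return an [image_volume()].
#' @export
read_image_series <- function(files, allow_irregular = FALSE) {
  if (length(files) == 0L) stop("empty file list")
  slices <- lapply(files, function(f) {
    ds <- dcm_read(f, read_pixel = TRUE)
    if (is.null(ds)) stop("not a DICOM file: ", f)
    ds
  })
  series_uids <- vapply(slices, .dcm_get_chr, "", "SeriesInstanceUID")
  if (length(unique(series_uids)) != 1L)
    stop("files span multiple series: ", paste(unique(series_uids), collapse = ", "))
  iop <- .dcm_get(slices[[1]], "ImageOrientationPatient")
  if (is.null(iop) || length(iop) != 6L)
    stop("missing ImageOrientationPatient in ", files[1])
  xdir <- iop[1:3]; ydir <- iop[4:6]
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  ipps <- t(vapply(slices, function(s) .dcm_get(s, "ImagePositionPatient"),
                   numeric(3)))
  proj <- drop(ipps %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; ipps <- ipps[ord, , drop = FALSE]; proj <- proj[ord]
  if (length(slices) > 1L) {
    gaps <- diff(proj)
    if (max(gaps) - min(gaps) > 1e-3 * mean(gaps)) {
      msg <- paste0("non-uniform inter-slice spacing; gaps [",
                    paste(signif(gaps, 6), collapse = ", "),
                    "] at sorted positions [",
                    paste(signif(proj, 6), collapse = ", "), "]")
      if (allow_irregular) warning(msg) else stop(msg)
    }
    dz <- mean(gaps)
  } else {
    dz <- .dcm_get(slices[[1]], "SliceThickness")
    dz <- if (is.null(dz) || !length(dz)) 1 else dz[1]
  }
  ps <- .dcm_get(slices[[1]], "PixelSpacing") # (row, col) = (dy, dx)
  rows <- .dcm_get(slices[[1]], "Rows"); cols <- .dcm_get(slices[[1]], "Columns")
  bits <- .dcm_get(slices[[1]], "BitsAllocated")
  signed <- isTRUE(.dcm_get(slices[[1]], "PixelRepresentation") == 1L)
  if (!identical(bits, 16L)) stop("only 16-bit pixel data is supported")
  nz <- length(slices)
  voxels <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    slope <- .dcm_get(s, "RescaleSlope"); icpt <- .dcm_get(s, "RescaleIntercept")
    slope <- if (is.null(slope) || !length(slope)) 1 else slope[1]
    icpt <- if (is.null(icpt) || !length(icpt)) 0 else icpt[1]
    nf <- .dcm_get(s, "NumberOfFrames")
    if (!is.null(nf) && length(nf) && nf[1] > 1L)
      stop("multi-frame image series are not supported; split ", s$path)
    stored <- readBin(.dcm_get(s, "PixelData"), "integer", n = rows * cols,
                      size = 2L, signed = signed, endian = "little")
    voxels[, , k] <- stored * slope + icpt
  }
  direction <- cbind(xdir, ydir, normal, deparse.level = 0)
  image_volume(voxels, origin = ipps[1, ], spacing = c(ps[2], ps[1], dz),
               direction = direction,
               modality = .dcm_get_chr(slices[[1]], "Modality", "CT"),
               intensity_units = if (.dcm_get_chr(slices[[1]], "Modality") == "CT")
                 "HU" else "arbitrary",
               frame_of_reference_uid = .dcm_get_chr(slices[[1]],
                                                     "FrameOfReferenceUID", NA))
}

#' Read an RT Structure Set
#'
#' ROI names are kept verbatim (byte for byte); contour points stay in
#' patient mm coordinates exactly as stored. Degenerate contours with
#' fewer than 3 points are dropped (with a message reporting the count);
#' an ROI with no contour data is retained with zero contours and flagged.
#'
#' @param file an RT Structure Set file.
#' @return a `structure_set`: list with `rois` (each `name`, `number`,
#'   `contours` = list of n x 3 mm matrices, `flag_empty`) and
#'   `referenced_series_uid` / `frame_of_reference_uid` when present.
#' @export
read_rtstruct <- function(file) {
  ds <- dcm_read(file, read_pixel = TRUE)
  if (is.null(ds)) stop("not a DICOM file: ", file)
  if (.dcm_get_chr(ds, "Modality") != "RTSTRUCT")
    stop("not an RT Structure Set: ", file)
  rec <- extract_record(file)
  roi_seq <- .dcm_get(ds, "StructureSetROISequence")
  cont_seq <- .dcm_get(ds, "ROIContourSequence")
  if (is.null(roi_seq)) roi_seq <- list()
  # ROI number -> contours
  conts_by_num <- list()
  n_dropped <- 0L
  for (item in (if (is.null(cont_seq)) list() else cont_seq)) {
    num <- item[[.dcm_dict$ReferencedROINumber$key]]$value
    cs <- item[[.dcm_dict$ContourSequence$key]]$value
    polys <- list()
    for (c_item in (if (is.null(cs)) list() else cs)) {
      pts <- c_item[[.dcm_dict$ContourData$key]]$value
      if (is.null(pts) || length(pts) < 9L) { n_dropped <- n_dropped + 1L; next }
      polys[[length(polys) + 1L]] <- matrix(pts, ncol = 3L, byrow = TRUE)
    }
    conts_by_num[[as.character(num)]] <- polys
  }
  if (n_dropped > 0L)
    message("dropped ", n_dropped, " degenerate contour(s) (< 3 points) in ", file)
  rois <- lapply(roi_seq, function(item) {
    num <- item[[.dcm_dict$ROINumber$key]]$value
    nm <- item[[.dcm_dict$ROIName$key]]$value
    polys <- conts_by_num[[as.character(num)]]
    if (is.null(polys)) polys <- list()
    list(name = if (is.null(nm)) "" else nm, number = num,
         contours = polys, flag_empty = length(polys) == 0L)
  })
  structure(list(rois = rois,
                 referenced_series_uid = rec$referenced_series_uid,
                 frame_of_reference_uid = rec$frame_of_reference_uid,
                 path = file),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROI(s)\n", length(x$rois)))
  for (r in x$rois)
    cat(sprintf("  [%d] %-20s %d contour(s)%s\n", r$number, r$name,
                length(r$contours), if (r$flag_empty) "  (empty)" else ""))
  invisible(x)
}

#' Read an RT Dose grid
#'
#' Stored integers are multiplied by the dose grid scaling factor so the
#' returned voxels are absorbed dose in Gy; slice offsets come from the
#' grid frame offset vector. A missing scaling factor is an error — it is
#' never silently assumed to be 1.
#'
#' @param file an RT Dose file with a 3-D grid.
#' @return a [dose_grid()].
#' @export
read_rtdose <- function(file) {
  ds <- dcm_read(file, read_pixel = TRUE)
  if (is.null(ds)) stop("not a DICOM file: ", file)
  if (.dcm_get_chr(ds, "Modality") != "RTDOSE")
    stop("not an RT Dose object: ", file)
  scaling <- .dcm_get(ds, "DoseGridScaling")
  if (is.null(scaling) || !length(scaling))
    stop("RT Dose without DoseGridScaling in ", file,
         "; refusing to assume 1.0")
  rows <- .dcm_get(ds, "Rows"); cols <- .dcm_get(ds, "Columns")
  nf <- .dcm_get(ds, "NumberOfFrames")
  if (is.null(nf) || !length(nf) || nf[1] < 1L)
    stop("RT Dose without a 3-D grid (NumberOfFrames) in ", file)
  nf <- nf[1]
  offsets <- .dcm_get(ds, "GridFrameOffsetVector")
  if (is.null(offsets) || length(offsets) != nf)
    stop("GridFrameOffsetVector missing or inconsistent in ", file)
  dz <- if (nf > 1L) {
    gaps <- diff(offsets)
    if (max(gaps) - min(gaps) > 1e-6 * mean(gaps))
      stop("non-uniform dose grid frame offsets in ", file)
    mean(gaps)
  } else 1
  ps <- .dcm_get(ds, "PixelSpacing")
  ipp <- .dcm_get(ds, "ImagePositionPatient")
  iop <- .dcm_get(ds, "ImageOrientationPatient")
  xdir <- iop[1:3]; ydir <- iop[4:6]
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  signed <- isTRUE(.dcm_get(ds, "PixelRepresentation") == 1L)
  bits <- .dcm_get(ds, "BitsAllocated")
  n <- rows * cols * nf
  raw <- .dcm_get(ds, "PixelData")
  stored <- if (identical(bits, 32L)) {
    readBin(raw, "integer", n = n, size = 4L, endian = "little")
  } else {
    readBin(raw, "integer", n = n, size = 2L, signed = signed, endian = "little")
  }
  voxels <- array(stored * scaling[1], c(cols, rows, nf))
  origin <- ipp + normal * offsets[1]
  dose_grid(voxels, origin = origin, spacing = c(ps[2], ps[1], dz),
            direction = cbind(xdir, ydir, normal, deparse.level = 0),
            frame_of_reference_uid = .dcm_get_chr(ds, "FrameOfReferenceUID", NA))
}
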