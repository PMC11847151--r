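# Deterministic synthetic DICOM-RT fixture datasets with analytic ground
# truth: per patient one CT series (one file per slice), an RT Structure Set
# outlining a known shape, and optionally an RT Plan and RT Dose grid wired
# through the standard DICOM-RT reference chain RTDOSE -> RTPLAN ->
# RTSTRUCT -> CT. Every UID derives from the seed, every pixel from the
# spec, so identical (spec, seed) pairs yield byte-identical trees.

.rtc_uid_root <- "1.2.826.0.1.3680043.9.7433."

.fixture_uid <- function(seed, patient, kind, i = 1L) {
  paste0(.rtc_uid_root, seed, ".", patient, ".", kind, ".", i)
}

#' Specify a synthetic DICOM-RT fixture dataset
#'
#' The defaults describe the package's canonical validation dataset: two
#' patients, a 64 x 64 x 48 voxel CT at 1 mm isotropic spacing with
#' background -1000 HU, and a 20 mm radius sphere of +100 HU (soft-tissue
#' like) centred in the grid, outlined by one ROI whose planar contours are
#' sampled at 1 degree steps. The optional dose grid is a linear gradient
#' along x on a coarser (2 mm) grid, scaled so the largest stored integer
#' is 5000; with the default `dose_scaling` of 0.01 the maximum dose is
#' exactly 50 Gy.
#'
#' @param n_patients number of patients (0 allowed: empty dataset).
#' @param slices_per_series CT slices per series.
#' @param rows,cols in-plane CT matrix size.
#' @param pixel_spacing in-plane (x, y) spacing in mm.
#' @param slice_thickness slice-to-slice spacing in mm.
#' @param shape `"sphere"` or `"cuboid"`.
#' @param shape_size sphere radius in mm, or cuboid edge lengths (length-3,
#'   mm).
#' @param roi_names names of the ROIs written to the structure set (all
#'   outline the same shape).
#' @param dose_scaling dose grid scaling factor (Gy per stored unit).
#' @param include_rtdose,include_rtplan write RT Dose / RT Plan objects
#'   (dose requires plan: the reference chain runs through it).
#' @param corruption `"none"`, `"drop_rtstruct_reference"` (remove the
#'   structure set's referenced-frame-of-reference sequence, severing the
#'   explicit RTSTRUCT to CT link) or `"drop_frame_of_reference"` (remove
#'   the structure set's frame of reference UID, disabling the
#'   frame-of-reference fallback too).
#' @param seed integer seed from which all UIDs derive.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_patients = 2L, slices_per_series = 48L,
                         rows = 64L, cols = 64L,
                         pixel_spacing = c(1, 1), slice_thickness = 1,
                         shape = c("sphere", "cuboid"), shape_size = 20,
                         roi_names = "GTV", dose_scaling = 0.01,
                         include_rtdose = FALSE, include_rtplan = FALSE,
                         corruption = c("none", "drop_rtstruct_reference",
                                        "drop_frame_of_reference"),
                         seed = 1L) {
  shape <- match.arg(shape)
  corruption <- match.arg(corruption)
  if (n_patients < 0 || slices_per_series < 1 || rows < 1 || cols < 1)
    stop("n_patients must be >= 0 and grid dimensions positive")
  if (any(pixel_spacing <= 0) || slice_thickness <= 0)
    stop("pixel_spacing and slice_thickness must be strictly positive")
  if (dose_scaling <= 0) stop("dose_scaling must be positive")
  if (shape == "cuboid" && length(shape_size) != 3L)
    stop("cuboid shape_size must be length 3 (mm edge lengths)")
  if (include_rtdose && !include_rtplan)
    stop("include_rtdose requires include_rtplan (the DICOM-RT chain runs through RTPLAN)")
  structure(list(n_patients = as.integer(n_patients),
                 slices_per_series = as.integer(slices_per_series),
                 rows = as.integer(rows), cols = as.integer(cols),
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = as.numeric(slice_thickness),
                 shape = shape, shape_size = as.numeric(shape_size),
                 roi_names = roi_names, dose_scaling = dose_scaling,
                 include_rtdose = include_rtdose,
                 include_rtplan = include_rtplan,
                 corruption = corruption, seed = as.integer(seed)),
            class = "fixture_spec")
}

.shape_center <- function(spec) {
  c(floor(spec$cols / 2) * spec$pixel_spacing[1],
    floor(spec$rows / 2) * spec$pixel_spacing[2],
    floor(spec$slices_per_series / 2) * spec$slice_thickness)
}

.shape_volume <- function(spec) {
  if (spec$shape == "sphere") 4 / 3 * pi * spec$shape_size[1]^3
  else prod(spec$shape_size)
}

# planar contours of the fixture shape: list of n x 3 matrices (patient mm),
# one per CT slice the shape intersects, coordinates rounded to 4 decimals
# (the precision they are written with)
.shape_contours <- function(spec, center) {
  zs <- (seq_len(spec$slices_per_series) - 1L) * spec$slice_thickness
  out <- list()
  if (spec$shape == "sphere") {
    r <- spec$shape_size[1]
    for (z in zs) {
      dz <- z - center[3]
      if (abs(dz) >= r) next
      rz <- sqrt(r^2 - dz^2)
      th <- (0:359) * pi / 180
      out[[length(out) + 1L]] <-
        round(cbind(center[1] + rz * cos(th), center[2] + rz * sin(th), z), 4)
    }
  } else {
    h <- spec$shape_size / 2
    for (z in zs) {
      if (abs(z - center[3]) > h[3]) next
      out[[length(out) + 1L]] <- round(cbind(
        center[1] + c(-h[1], h[1], h[1], -h[1]),
        center[2] + c(-h[2], -h[2], h[2], h[2]), z), 4)
    }
  }
  out
}

.shape_interior <- function(spec, center, x, y, z) {
  if (spec$shape == "sphere") {
    (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <=
      spec$shape_size[1]^2
  } else {
    h <- spec$shape_size / 2
    abs(x - center[1]) <= h[1] & abs(y - center[2]) <= h[2] &
      abs(z - center[3]) <= h[3]
  }
}

.fixture_common_els <- function(patient_id, study_uid, spec) {
  list(dcm_el("SpecificCharacterSet", "ISO_IR 100"),
       dcm_el("PatientID", patient_id),
       dcm_el("PatientName", paste0("Synthetic^", patient_id)),
       dcm_el("StudyInstanceUID", study_uid),
       dcm_el("StudyID", "1"),
       dcm_el("StudyDate", "20200101"),
       dcm_el("StudyTime", "000000"))
}

.write_fixture_ct <- function(dir, spec, p, pid, study_uid, for_uid,
                              series_uid, sop_uids, center) {
  dx <- spec$pixel_spacing[1]; dy <- spec$pixel_spacing[2]
  xs <- (seq_len(spec$cols) - 1L) * dx
  ys <- (seq_len(spec$rows) - 1L) * dy
  gx <- matrix(xs, spec$cols, spec$rows)
  gy <- matrix(ys, spec$cols, spec$rows, byrow = TRUE)
  files <- character(spec$slices_per_series)
  for (k in seq_len(spec$slices_per_series)) {
    z <- (k - 1L) * spec$slice_thickness
    hu <- ifelse(.shape_interior(spec, center, gx, gy, z), 100, -1000)
    stored <- as.integer(hu + 1024) # rescale intercept -1024, slope 1
    els <- c(.fixture_common_els(pid, study_uid, spec), list(
      dcm_el("SOPClassUID", DCM_UID$CTImageStorage),
      dcm_el("SOPInstanceUID", sop_uids[k]),
      dcm_el("Modality", "CT"),
      dcm_el("ImageType", c("ORIGINAL", "PRIMARY", "AXIAL")),
      dcm_el("SeriesInstanceUID", series_uid),
      dcm_el("SeriesNumber", 1L),
      dcm_el("SeriesDate", "20200101"),
      dcm_el("InstanceNumber", k),
      dcm_el("FrameOfReferenceUID", for_uid),
      dcm_el("ImagePositionPatient", c(0, 0, z)),
      dcm_el("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
      dcm_el("PixelSpacing", c(dy, dx)), # DICOM order: row, then column
      dcm_el("SliceThickness", spec$slice_thickness),
      dcm_el("Rows", spec$rows), dcm_el("Columns", spec$cols),
      dcm_el("SamplesPerPixel", 1L),
      dcm_el("PhotometricInterpretation", "MONOCHROME2"),
      dcm_el("BitsAllocated", 16L), dcm_el("BitsStored", 16L),
      dcm_el("HighBit", 15L), dcm_el("PixelRepresentation", 1L),
      dcm_el("RescaleIntercept", -1024), dcm_el("RescaleSlope", 1),
      dcm_el("PixelData", writeBin(stored, raw(), size = 2L, endian = "little"))))
    rel <- file.path(pid, "imaging", "slices", sprintf("CT_%03d.dcm", k))
    dir.create(dirname(file.path(dir, rel)), recursive = TRUE, showWarnings = FALSE)
    dcm_write(file.path(dir, rel), els)
    files[k] <- rel
  }
  files
}

.write_fixture_rtstruct <- function(dir, spec, pid, study_uid, for_uid,
                                    ct_series_uid, ct_sop_uids,
                                    series_uid, sop_uid, center) {
  contours <- .shape_contours(spec, center)
  roi_items <- list(); cont_items <- list()
  for (ri in seq_along(spec$roi_names)) {
    roi_items[[ri]] <- list(
      dcm_el("ROINumber", ri),
      dcm_el("ReferencedFrameOfReferenceUID", for_uid),
      dcm_el("ROIName", spec$roi_names[ri]),
      dcm_el("ROIGenerationAlgorithm", "AUTOMATIC"))
    cseq <- lapply(contours, function(m) list(
      dcm_el("ContourGeometricType", "CLOSED_PLANAR"),
      dcm_el("NumberOfContourPoints", nrow(m)),
      dcm_el("ContourData", sprintf("%.4f", as.vector(t(m))))))
    cont_items[[ri]] <- list(
      dcm_el("ReferencedROINumber", ri),
      dcm_el("ContourSequence", cseq))
  }
  ref_for_seq <- list(list(
    dcm_el("FrameOfReferenceUID", for_uid),
    dcm_el("RTReferencedStudySequence", list(list(
      dcm_el("ReferencedSOPClassUID", DCM_UID$StudyComponent),
      dcm_el("ReferencedSOPInstanceUID", study_uid),
      dcm_el("RTReferencedSeriesSequence", list(list(
        dcm_el("SeriesInstanceUID", ct_series_uid),
        dcm_el("ContourImageSequence", lapply(ct_sop_uids, function(u) list(
          dcm_el("ReferencedSOPClassUID", DCM_UID$CTImageStorage),
          dcm_el("ReferencedSOPInstanceUID", u))))))))))))
  els <- c(.fixture_common_els(pid, study_uid, spec), list(
    dcm_el("SOPClassUID", DCM_UID$RTStructStorage),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTSTRUCT"),
    dcm_el("SeriesInstanceUID", series_uid),
    dcm_el("SeriesNumber", 2L),
    dcm_el("SeriesDate", "20200101"),
    dcm_el("FrameOfReferenceUID", for_uid),
    dcm_el("StructureSetLabel", "SyntheticStructs"),
    dcm_el("StructureSetDate", "20200101"),
    dcm_el("ReferencedFrameOfReferenceSequence", ref_for_seq),
    dcm_el("StructureSetROISequence", roi_items),
    dcm_el("ROIContourSequence", cont_items)))
  rel <- file.path("rtstructs", paste0(pid, "_struct.dcm"))
  dir.create(dirname(file.path(dir, rel)), recursive = TRUE, showWarnings = FALSE)
  dcm_write(file.path(dir, rel), els)
  rel
}

.write_fixture_rtplan <- function(dir, spec, pid, study_uid, for_uid,
                                  struct_sop_uid, series_uid, sop_uid) {
  els <- c(.fixture_common_els(pid, study_uid, spec), list(
    dcm_el("SOPClassUID", DCM_UID$RTPlanStorage),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTPLAN"),
    dcm_el("SeriesInstanceUID", series_uid),
    dcm_el("SeriesNumber", 3L),
    dcm_el("SeriesDate", "20200101"),
    dcm_el("FrameOfReferenceUID", for_uid),
    dcm_el("RTPlanLabel", "SyntheticPlan"),
    dcm_el("RTPlanDate", "20200101"),
    dcm_el("ReferencedStructureSetSequence", list(list(
      dcm_el("ReferencedSOPClassUID", DCM_UID$RTStructStorage),
      dcm_el("ReferencedSOPInstanceUID", struct_sop_uid))))))
  rel <- file.path(pid, "plan", "plan.dcm")
  dir.create(dirname(file.path(dir, rel)), recursive = TRUE, showWarnings = FALSE)
  dcm_write(file.path(dir, rel), els)
  rel
}

# dose grid geometry derived from the CT extent: 2 mm isotropic, covering
# the full CT physical extent from the same origin
.fixture_dose_geom <- function(spec) {
  sp <- 2
  ext <- c((spec$cols - 1L) * spec$pixel_spacing[1],
           (spec$rows - 1L) * spec$pixel_spacing[2],
           (spec$slices_per_series - 1L) * spec$slice_thickness)
  dims <- as.integer(ceiling(ext / sp)) + 1L
  list(spacing = c(sp, sp, sp), dims = dims, origin = c(0, 0, 0))
}

.write_fixture_rtdose <- function(dir, spec, pid, study_uid, for_uid,
                                  plan_sop_uid, series_uid, sop_uid) {
  g <- .fixture_dose_geom(spec)
  x_max <- (g$dims[1] - 1L) * g$spacing[1]
  dose_base <- 10
  gradient <- (5000 * spec$dose_scaling - dose_base) / x_max
  xs <- (seq_len(g$dims[1]) - 1L) * g$spacing[1]
  stored_col <- as.integer(round((dose_base + gradient * xs) / spec$dose_scaling))
  stored <- array(stored_col, g$dims) # constant over y, z
  els <- c(.fixture_common_els(pid, study_uid, spec), list(
    dcm_el("SOPClassUID", DCM_UID$RTDoseStorage),
    dcm_el("SOPInstanceUID", sop_uid),
    dcm_el("Modality", "RTDOSE"),
    dcm_el("SeriesInstanceUID", series_uid),
    dcm_el("SeriesNumber", 4L),
    dcm_el("SeriesDate", "20200101"),
    dcm_el("FrameOfReferenceUID", for_uid),
    dcm_el("ImagePositionPatient", g$origin),
    dcm_el("ImageOrientationPatient", c(1, 0, 0, 0, 1, 0)),
    dcm_el("PixelSpacing", g$spacing[c(2, 1)]),
    dcm_el("SliceThickness", g$spacing[3]),
    dcm_el("Rows", g$dims[2]), dcm_el("Columns", g$dims[1]),
    dcm_el("NumberOfFrames", g$dims[3]),
    dcm_el("GridFrameOffsetVector", (seq_len(g$dims[3]) - 1L) * g$spacing[3]),
    dcm_el("SamplesPerPixel", 1L),
    dcm_el("PhotometricInterpretation", "MONOCHROME2"),
    dcm_el("BitsAllocated", 16L), dcm_el("BitsStored", 16L),
    dcm_el("HighBit", 15L), dcm_el("PixelRepresentation", 0L),
    dcm_el("DoseUnits", "GY"), dcm_el("DoseType", "PHYSICAL"),
    dcm_el("DoseSummationType", "PLAN"),
    dcm_el("DoseGridScaling", spec$dose_scaling),
    dcm_el("ReferencedRTPlanSequence", list(list(
      dcm_el("ReferencedSOPClassUID", DCM_UID$RTPlanStorage),
      dcm_el("ReferencedSOPInstanceUID", plan_sop_uid)))),
    dcm_el("PixelData",
           writeBin(as.integer(stored), raw(), size = 2L, endian = "little"))))
  rel <- file.path("doses", paste0(pid, "_dose.dcm"))
  dir.create(dirname(file.path(dir, rel)), recursive = TRUE, showWarnings = FALSE)
  dcm_write(file.path(dir, rel), els)
  list(rel = rel, dose_base = dose_base, gradient = gradient,
       max_gy = 5000 * spec$dose_scaling, geom = g)
}

#' Generate a synthetic DICOM-RT fixture dataset
#'
#' Writes standard DICOM Part-10 files (CT Image Storage plus RT Structure
#' Set / Plan / Dose Storage) under `out_dir`, in deliberately mixed nested
#' folders (CT slices inside patient folders, structure sets and doses in
#' shared top-level folders) to exercise recursive crawling. A
#' `manifest.json` with every generated UID, file path and the analytic
#' ground truth is written at the root and returned.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory; must be absent or empty unless
#'   `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return a `fixture_manifest` object (invisibly written as
#'   `manifest.json`).
#' @export
generate_dataset <- function(spec, out_dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                               no.. = TRUE)) > 0 && !overwrite)
    stop("out_dir is not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  center <- .shape_center(spec)
  patients <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    uid <- function(kind, i = 1L) .fixture_uid(spec$seed, p, kind, i)
    study_uid <- uid(1L); for_uid <- uid(4L)
    ct_series <- uid(2L)
    ct_sops <- vapply(seq_len(spec$slices_per_series),
                      function(k) uid(3L, k), "")
    ct_files <- .write_fixture_ct(out_dir, spec, p, pid, study_uid, for_uid,
                                  ct_series, ct_sops, center)
    rs_series <- uid(5L); rs_sop <- uid(6L)
    rs_file <- .write_fixture_rtstruct(out_dir, spec, pid, study_uid, for_uid,
                                       ct_series, ct_sops, rs_series, rs_sop,
                                       center)
    rec <- list(patient_id = pid, study_uid = study_uid,
                frame_of_reference_uid = for_uid,
                ct_series_uid = ct_series, ct_sop_uids = ct_sops,
                ct_files = ct_files,
                rtstruct_series_uid = rs_series, rtstruct_sop_uid = rs_sop,
                rtstruct_file = rs_file)
    if (spec$include_rtplan) {
      pl_series <- uid(7L); pl_sop <- uid(8L)
      rec$rtplan_series_uid <- pl_series; rec$rtplan_sop_uid <- pl_sop
      rec$rtplan_file <- .write_fixture_rtplan(out_dir, spec, pid, study_uid,
                                               for_uid, rs_sop, pl_series, pl_sop)
    }
    if (spec$include_rtdose) {
      do_series <- uid(9L); do_sop <- uid(10L)
      d <- .write_fixture_rtdose(out_dir, spec, pid, study_uid, for_uid,
                                 rec$rtplan_sop_uid, do_series, do_sop)
      rec$rtdose_series_uid <- do_series; rec$rtdose_sop_uid <- do_sop
      rec$rtdose_file <- d$rel
      rec$dose <- list(base_gy = d$dose_base, gradient_x_gy_per_mm = d$gradient,
                       max_gy = d$max_gy, scaling = spec$dose_scaling,
                       origin = d$geom$origin, spacing = d$geom$spacing,
                       dims = d$geom$dims)
    }
    patients[[pid]] <- rec
  }
  manifest <- structure(list(
    root = normalizePath(out_dir),
    spec = unclass(spec),
    ground_truth = list(shape = spec$shape, shape_size = spec$shape_size,
                        center_mm = center,
                        analytic_volume_mm3 = .shape_volume(spec),
                        hu_interior = 100, hu_background = -1000,
                        roi_names = spec$roi_names),
    patients = patients,
    severed = list()), class = "fixture_manifest")
  if (spec$corruption != "none")
    manifest <- corrupt_dataset(manifest, spec$corruption)
  .write_manifest_json(manifest)
  manifest
}

# root is deliberately omitted from the JSON: it is the directory holding
# the file, so the serialized manifest is byte-identical wherever the
# dataset is generated
.write_manifest_json <- function(manifest) {
  m <- unclass(manifest)
  m$root <- NULL
  jsonlite::write_json(m, file.path(manifest$root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Load a fixture manifest back from a generated dataset directory
#'
#' @param dir a directory written by [generate_dataset()].
#' @return the `fixture_manifest`.
#' @export
load_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json under ", dir)
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  m$root <- normalizePath(dir)
  m$patients <- lapply(m$patients, function(p) {
    p$ct_sop_uids <- unlist(p$ct_sop_uids); p$ct_files <- unlist(p$ct_files); p
  })
  structure(m, class = "fixture_manifest")
}

#' Sever reference metadata in a generated fixture dataset
#'
#' Rewrites the targeted RT Structure Set files with the named reference
#' attribute removed (a byte-exact splice of that one element), emulating
#' the corrupted or missing metadata found in clinical archives. Modes:
#' `drop_rtstruct_reference` removes the referenced-frame-of-reference
#' sequence (the explicit RTSTRUCT to CT series link);
#' `drop_frame_of_reference` removes the frame of reference UID (so the
#' frame-of-reference fallback heuristic also fails); `none` is the
#' identity.
#'
#' @param manifest a `fixture_manifest` from [generate_dataset()].
#' @param mode corruption mode (see above).
#' @param patient_ids patients to corrupt; default all.
#' @return the manifest, with `severed` recording each removed link as
#'   `"<patient>:<mode>"`.
#' @export
corrupt_dataset <- function(manifest, mode, patient_ids = NULL) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  modes <- c("none", "drop_rtstruct_reference", "drop_frame_of_reference")
  if (!mode %in% modes)
    stop("unknown corruption mode '", mode, "'; expected one of: ",
         paste(modes, collapse = ", "))
  if (mode == "none") return(manifest)
  if (is.null(patient_ids)) patient_ids <- names(manifest$patients)
  tag <- switch(mode,
                drop_rtstruct_reference = "ReferencedFrameOfReferenceSequence",
                drop_frame_of_reference = "FrameOfReferenceUID")
  for (pid in patient_ids) {
    rec <- manifest$patients[[pid]]
    if (is.null(rec)) stop("unknown patient id: ", pid)
    dcm_strip_tag(file.path(manifest$root, rec$rtstruct_file), tag)
    manifest$severed[[length(manifest$severed) + 1L]] <- paste0(pid, ":", mode)
  }
  .write_manifest_json(manifest)
  manifest
}
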