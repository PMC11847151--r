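# Stage 1, "crawl": recursively open every DICOM file under a root and
# aggregate the linking metadata into a series-level index. Only headers
# are read (PixelData is seeked over), which is what keeps the index a
# few-kilobytes artifact that can be shared instead of re-crawled.

INDEX_FORMAT_VERSION <- "1.0"

.file_record_cols <- c("path", "patient_id", "study_uid", "series_uid",
                       "sop_instance_uid", "modality",
                       "frame_of_reference_uid", "referenced_series_uid",
                       "referenced_plan_uid", "referenced_structset_uid",
                       "series_date", "ipp_x", "ipp_y", "ipp_z",
                       "iop", "spacing_row", "spacing_col")

.empty_file_records <- function() {
  df <- as.data.frame(stats::setNames(
    lapply(.file_record_cols, function(nm)
      if (nm %in% c("ipp_x", "ipp_y", "ipp_z", "spacing_row", "spacing_col"))
        numeric(0) else character(0)),
    .file_record_cols))
  df
}

#' Extract one file's linking metadata
#'
#' Opens a single DICOM file (header only) and pulls out the identifiers
#' and cross-modality references needed to connect and process it: patient,
#' study, series and SOP instance UIDs, modality, frame of reference, and
#' the modality-specific reference chain (RTSTRUCT: referenced CT/MR series
#' from the nested referenced-frame-of-reference / study / series
#' sequences; RTDOSE: referenced plan SOP instance; RTPLAN: referenced
#' structure set SOP instance). Missing optional attributes yield `NA`
#' fields, never failure.
#'
#' @param file path to one file.
#' @return a one-row data.frame, or `NULL` (the skip marker) when the file
#'   has no DICOM preamble. Unreadable paths throw.
#' @export
extract_record <- function(file) {
  ds <- dcm_read(file, read_pixel = FALSE)
  if (is.null(ds)) return(NULL)
  modality <- .dcm_get_chr(ds, "Modality", "other")
  series_uid <- .dcm_get_chr(ds, "SeriesInstanceUID")
  sop_uid <- .dcm_get_chr(ds, "SOPInstanceUID")
  if (is.na(series_uid) || is.na(sop_uid)) return(NULL)
  study_uid <- .dcm_get_chr(ds, "StudyInstanceUID", "")
  patient <- .dcm_get_chr(ds, "PatientID")
  if (is.na(patient))
    patient <- paste0("UNKNOWN_", substr(study_uid, 1, 16))
  for_uid <- .dcm_get_chr(ds, "FrameOfReferenceUID")
  ref_series <- NA_character_
  ref_plan <- NA_character_
  ref_structset <- NA_character_
  if (modality == "RTSTRUCT") {
    rfor <- .dcm_get(ds, "ReferencedFrameOfReferenceSequence")
    if (!is.null(rfor) && length(rfor)) {
      item <- rfor[[1]]
      if (is.na(for_uid)) {
        v <- item[[.dcm_dict$FrameOfReferenceUID$key]]$value
        if (!is.null(v) && nzchar(v)) for_uid <- v
      }
      study_seq <- item[[.dcm_dict$RTReferencedStudySequence$key]]$value
      if (!is.null(study_seq) && length(study_seq)) {
        series_seq <- study_seq[[1]][[.dcm_dict$RTReferencedSeriesSequence$key]]$value
        if (!is.null(series_seq) && length(series_seq)) {
          v <- series_seq[[1]][[.dcm_dict$SeriesInstanceUID$key]]$value
          if (!is.null(v) && nzchar(v)) ref_series <- v
        }
      }
    }
  } else if (modality == "RTDOSE") {
    seq <- .dcm_get(ds, "ReferencedRTPlanSequence")
    if (!is.null(seq) && length(seq)) {
      v <- seq[[1]][[.dcm_dict$ReferencedSOPInstanceUID$key]]$value
      if (!is.null(v) && nzchar(v)) ref_plan <- v
    }
  } else if (modality == "RTPLAN") {
    seq <- .dcm_get(ds, "ReferencedStructureSetSequence")
    if (!is.null(seq) && length(seq)) {
      v <- seq[[1]][[.dcm_dict$ReferencedSOPInstanceUID$key]]$value
      if (!is.null(v) && nzchar(v)) ref_structset <- v
    }
  }
  ipp <- .dcm_get(ds, "ImagePositionPatient")
  if (is.null(ipp) || length(ipp) != 3L) ipp <- rep(NA_real_, 3L)
  iop <- .dcm_get(ds, "ImageOrientationPatient")
  iop <- if (is.null(iop) || length(iop) != 6L) NA_character_ else
    paste(sprintf("%.8g", iop), collapse = ";")
  ps <- .dcm_get(ds, "PixelSpacing")
  if (is.null(ps) || length(ps) != 2L) ps <- rep(NA_real_, 2L)
  data.frame(path = file, patient_id = patient, study_uid = study_uid,
             series_uid = series_uid, sop_instance_uid = sop_uid,
             modality = modality, frame_of_reference_uid = for_uid,
             referenced_series_uid = ref_series,
             referenced_plan_uid = ref_plan,
             referenced_structset_uid = ref_structset,
             series_date = .dcm_get_chr(ds, "SeriesDate",
                                        .dcm_get_chr(ds, "StudyDate", "")),
             ipp_x = ipp[1], ipp_y = ipp[2], ipp_z = ipp[3],
             iop = iop, spacing_row = ps[1], spacing_col = ps[2])
}

.first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[1] else NA_character_
}

# aggregate per-file records (paths already relative) into the series table
.series_table <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(series_uid = character(0), patient_id = character(0),
                      study_uid = character(0), modality = character(0),
                      frame_of_reference_uid = character(0),
                      referenced_series_uid = character(0),
                      referenced_plan_uid = character(0),
                      referenced_structset_uid = character(0),
                      series_date = character(0),
                      n_files = integer(0), file_paths = character(0)))
  }
  rel <- records$path
  sp <- split(seq_len(nrow(records)), records$series_uid)
  rows <- lapply(sp, function(ix) {
    r <- records[ix, , drop = FALSE]
    ord <- order(r$sop_instance_uid, method = "radix")
    data.frame(series_uid = r$series_uid[1],
               patient_id = r$patient_id[1],
               study_uid = r$study_uid[1],
               modality = r$modality[1],
               frame_of_reference_uid = .first_non_na(r$frame_of_reference_uid),
               referenced_series_uid = .first_non_na(r$referenced_series_uid),
               referenced_plan_uid = .first_non_na(r$referenced_plan_uid),
               referenced_structset_uid = .first_non_na(r$referenced_structset_uid),
               series_date = r$series_date[1],
               n_files = nrow(r),
               file_paths = paste(rel[ix][ord], collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$series_uid, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.relative_to <- function(paths, root) {
  root <- paste0(sub("/+$", "", normalizePath(root, winslash = "/")), "/")
  p <- normalizePath(paths, winslash = "/", mustWork = FALSE)
  ifelse(startsWith(p, root), substring(p, nchar(root) + 1L), p)
}

#' Crawl a directory tree of DICOM files into a dataset index
#'
#' Recursively opens every regular file under `root` (any depth, any folder
#' organization), keeps the ones with a DICOM preamble, and aggregates
#' their metadata into a series-level index. The result is a pure function
#' of the file contents: records are sorted by (patient, series, SOP
#' instance), so traversal order and worker count never change the output.
#'
#' @param root directory to crawl.
#' @param n_workers parallel workers (forked; each worker parses a disjoint
#'   set of files, results are reduced by a deterministic sort).
#' @return a `dataset_index`: `file_records` (one row per DICOM file),
#'   `series` (one row per series with a semicolon-joined relative file
#'   list), `crawl_root`, `n_skipped`, `format_version`.
#' @export
crawl_directory <- function(root, n_workers = 1L) {
  if (!dir.exists(root)) stop("crawl root does not exist: ", root)
  rel <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  # the tool's own index/report folder is never part of the dataset
  rel <- rel[!startsWith(rel, ".imgtools/") & !startsWith(rel, ".imgtools\\")]
  files <- file.path(root, rel)
  files <- files[file.exists(files) & !dir.exists(files)]
  one <- function(f) tryCatch(extract_record(f), error = function(e) {
    message("skipping unreadable file ", f, ": ", conditionMessage(e))
    NULL
  })
  recs <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, one, mc.cores = n_workers)
  } else lapply(files, one)
  keep <- !vapply(recs, is.null, TRUE)
  n_skipped <- sum(!keep)
  records <- if (any(keep)) do.call(rbind, recs[keep]) else .empty_file_records()
  if (nrow(records)) {
    records$path <- .relative_to(records$path, root)
    records <- records[order(records$patient_id, records$series_uid,
                             records$sop_instance_uid, method = "radix"), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(file_records = records,
                 series = .series_table(records),
                 crawl_root = normalizePath(root),
                 n_skipped = n_skipped,
                 format_version = INDEX_FORMAT_VERSION),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d files in %d series (%d non-DICOM skipped)\n",
              nrow(x$file_records), nrow(x$series), x$n_skipped))
  if (nrow(x$series))
    print(table(x$series$modality))
  invisible(x)
}

#' Save a dataset index
#'
#' Writes the shareable index artifact: `series.csv` (one row per series,
#' the few-kilobytes table to attach to a published dataset), `files.csv`
#' (per-file detail) and `index.json` (crawl root, format version, skip
#' count). The default location used by the pipeline is an `.imgtools`
#' folder at the crawled root.
#'
#' @param index a `dataset_index`.
#' @param path directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "dataset_index"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(index$series, file.path(path, "series.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(index$file_records, file.path(path, "files.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(list(format_version = index$format_version,
                            crawl_root = index$crawl_root,
                            n_skipped = index$n_skipped),
                       file.path(path, "index.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a previously saved dataset index
#'
#' Reconstructs an index saved by [save_index()] so that downstream
#' connecting and processing behave exactly as with a fresh crawl (the
#' pre-crawled database workflow: share the index, skip the crawl).
#'
#' @param path the directory written by [save_index()].
#' @param root optional override for the crawl root recorded in the index
#'   (use when the DICOM tree was moved).
#' @return a `dataset_index`.
#' @export
load_index <- function(path, root = NULL) {
  jf <- file.path(path, "index.json")
  if (!file.exists(jf)) stop("no index.json under ", path)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(meta$format_version, INDEX_FORMAT_VERSION))
    stop("index format version ", meta$format_version,
         " is incompatible with this package's version ", INDEX_FORMAT_VERSION)
  read_idx_csv <- function(f, num_cols) {
    df <- tryCatch(
      utils::read.csv(f, colClasses = "character", na.strings = NULL),
      error = function(e) stop("malformed index CSV ", f, ": ",
                               conditionMessage(e)))
    for (nm in intersect(num_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
    for (nm in setdiff(names(df), num_cols)) df[[nm]][df[[nm]] == ""] <- NA_character_
    df
  }
  records <- read_idx_csv(file.path(path, "files.csv"),
                          c("ipp_x", "ipp_y", "ipp_z", "spacing_row", "spacing_col"))
  series <- read_idx_csv(file.path(path, "series.csv"), c("n_files"))
  series$n_files <- as.integer(series$n_files)
  # empty-but-valid CSVs produce zero-row frames with the right columns
  series$study_uid[is.na(series$study_uid)] <- ""
  if (nrow(records)) records$study_uid[is.na(records$study_uid)] <- ""
  if (nrow(series)) {
    sd <- series$series_date; sd[is.na(sd)] <- ""
    series$series_date <- sd
  }
  structure(list(file_records = records, series = series,
                 crawl_root = if (is.null(root)) meta$crawl_root else
                   normalizePath(root),
                 n_skipped = meta$n_skipped,
                 format_version = meta$format_version),
            class = "dataset_index")
}
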