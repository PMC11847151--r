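# The single-command orchestrator: crawl (or load a pre-crawled index),
# connect, process every sample, write outputs plus a run manifest.
# Outputs are a pure function of (dataset bytes, configuration): no clocks
# or traversal order leak into them, so runs are byte-identical across
# repeats and worker counts.

#' Pipeline configuration
#'
#' @param input_dir directory of DICOM files to curate.
#' @param output_dir where analysis-ready volumes are written; must differ
#'   from `input_dir`.
#' @param modalities comma-separated modality query (default
#'   `"CT,RTSTRUCT"`).
#' @param heuristic linking heuristic for [build_graph()].
#' @param processing a [processing_params()].
#' @param n_workers parallel workers for crawling and per-sample
#'   processing.
#' @param nnunet also emit an nnU-Net style layout (see
#'   [export_nnunet()]); requires `processing$roi_patterns`.
#' @param nnunet_task task name used in nnU-Net file names.
#' @param preloaded_index optional path to a saved index directory; when
#'   set the crawl stage is skipped entirely.
#' @param index_dir where to save the index and reports (default
#'   `<input_dir>/.imgtools`; set this when the input tree is read-only).
#' @param overwrite_policy `"error"` (abort before writing if a sample
#'   output directory already has content), `"skip_existing"` (leave
#'   existing sample outputs untouched) or `"overwrite"`.
#' @param dedup sample multiplicity policy, see [query_samples()].
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            modalities = "CT,RTSTRUCT",
                            heuristic = c("metadata", "frame_of_reference",
                                          "study"),
                            processing = processing_params(),
                            n_workers = 1L, nnunet = FALSE,
                            nnunet_task = "TASK",
                            preloaded_index = NULL, index_dir = NULL,
                            overwrite_policy = c("error", "skip_existing",
                                                 "overwrite"),
                            dedup = c("none", "latest")) {
  heuristic <- match.arg(heuristic)
  overwrite_policy <- match.arg(overwrite_policy)
  dedup <- match.arg(dedup)
  stopifnot(inherits(processing, "processing_params"))
  if (normalizePath(input_dir, mustWork = FALSE) ==
      normalizePath(output_dir, mustWork = FALSE))
    stop("input_dir and output_dir must differ")
  if (n_workers < 1L) stop("n_workers must be >= 1")
  .parse_modalities(modalities) # validate tokens early
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 modalities = modalities, heuristic = heuristic,
                 processing = processing, n_workers = as.integer(n_workers),
                 nnunet = nnunet, nnunet_task = nnunet_task,
                 preloaded_index = preloaded_index, index_dir = index_dir,
                 overwrite_policy = overwrite_policy, dedup = dedup),
            class = "pipeline_config")
}

.rtcurate_version <- function() {
  tryCatch(as.character(utils::packageVersion("rtcurate")),
           error = function(e) "0.1.0")
}

# md5 of the serialized series table: the index identity recorded in the
# run manifest (clock-free)
.index_checksum <- function(index) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(index$series, tf, row.names = FALSE, na = "")
  unname(tools::md5sum(tf))
}

# process one sample: read members, transform, write volumes; returns a
# manifest row
.process_sample <- function(sample, index, config) {
  pp <- config$processing
  out_dir <- file.path(config$output_dir, sample$patient_id, sample$sample_id)
  mods <- names(sample$members)
  img_mod <- intersect(mods, .image_modalities)[1]
  if (is.na(img_mod)) stop("sample has no image series member")
  paths <- file.path(index$crawl_root, sample$members[[img_mod]]$file_paths)
  vol <- read_image_series(paths)
  if (!is.null(pp$target_spacing))
    vol <- resample(vol, pp$target_spacing, pp$image_interp)
  if (!is.null(pp$window))
    vol <- window_intensity(vol, pp$window[1], pp$window[2])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  p <- file.path(out_dir, paste0(img_mod, ".nii.gz"))
  write_volume(vol, p, "nifti")
  outputs <- c(outputs, p)
  if ("RTSTRUCT" %in% mods) {
    ss <- read_rtstruct(file.path(index$crawl_root,
                                  sample$members$RTSTRUCT$file_paths[1]))
    mask <- rasterize(ss, vol, pp)
    for (nm in names(mask$label_map)) {
      lab <- mask$label_map[[nm]]
      bin <- mask
      bin$voxels <- array(as.integer(mask$voxels == lab), dim(mask$voxels))
      p <- file.path(out_dir, paste0("mask_", gsub("[^A-Za-z0-9_.-]", "_", nm),
                                     ".nii.gz"))
      write_volume(bin, p, "nifti")
      outputs <- c(outputs, p)
    }
  }
  if ("RTDOSE" %in% mods) {
    dg <- read_rtdose(file.path(index$crawl_root,
                                sample$members$RTDOSE$file_paths[1]))
    ad <- align_dose(dg, vol, pp$image_interp)
    p <- file.path(out_dir, "RTDOSE.nii.gz")
    write_volume(ad, p, "nifti")
    outputs <- c(outputs, p)
  }
  outputs
}

.sample_member_string <- function(sample) {
  paste(vapply(names(sample$members), function(m)
    paste0(m, "=", sample$members[[m]]$series_uid), ""), collapse = ";")
}

#' Run the full curation pipeline
#'
#' Executes the three stages in order: crawl `input_dir` (or load a
#' pre-crawled index), connect series into samples under the configured
#' heuristic, and process every sample into analysis-ready NIfTI volumes
#' under `output_dir/<patient>/<sample_id>/`. Per-sample failures are
#' recorded in the returned manifest and never abort the run. The index,
#' an unmatched-series report and a run log are written under the index
#' directory (`.imgtools` at the input root by default); the output tree
#' itself contains only volumes, `manifest.csv` and `run_info.json`, all
#' byte-deterministic.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest data.frame (one row per sample: `sample_id`,
#'   `patient_id`, `members`, `outputs`, `status`, `reason`), invisibly,
#'   with attribute `n_failed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$input_dir))
    stop("input_dir does not exist: ", config$input_dir)
  index_dir <- config$index_dir %||% file.path(config$input_dir, ".imgtools")
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (!is.null(config$preloaded_index)) {
    log("loading pre-crawled index from ", config$preloaded_index)
    index <- load_index(config$preloaded_index, root = config$input_dir)
  } else {
    log("crawling ", config$input_dir)
    index <- crawl_directory(config$input_dir, config$n_workers)
    tryCatch(save_index(index, index_dir),
             error = function(e) warning("could not save index under ",
                                         index_dir, ": ", conditionMessage(e)))
  }
  log(nrow(index$file_records), " DICOM files in ", nrow(index$series),
      " series; ", index$n_skipped, " non-DICOM skipped")
  graph <- build_graph(index, config$heuristic)
  samples <- query_samples(graph, config$modalities, config$dedup)
  unmatched <- report_unmatched(graph, config$modalities)
  unmatched_path <- file.path(index_dir, "unmatched.csv")
  tryCatch({
    dir.create(index_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(unmatched, unmatched_path, row.names = FALSE)
  }, error = function(e) NULL)
  log(length(samples), " sample(s) for query '", config$modalities,
      "' under heuristic '", config$heuristic, "'; ", nrow(unmatched),
      " unmatched series")
  if (length(samples) == 0L)
    stop("no samples found for query '", config$modalities,
         "'; see unmatched report at ", unmatched_path)
  sample_dirs <- vapply(samples, function(s)
    file.path(config$output_dir, s$patient_id, s$sample_id), "")
  existing <- dir.exists(sample_dirs) &
    vapply(sample_dirs, function(d) length(list.files(d)) > 0L, TRUE)
  if (config$overwrite_policy == "error" && any(existing))
    stop("output collision (overwrite_policy = 'error'): ",
         paste(sample_dirs[existing], collapse = ", "))
  todo <- if (config$overwrite_policy == "skip_existing") !existing else
    rep(TRUE, length(samples))
  one <- function(i) {
    s <- samples[[i]]
    if (!todo[i])
      return(list(outputs = list.files(sample_dirs[i], full.names = TRUE),
                  status = "ok", reason = "skipped existing"))
    tryCatch(list(outputs = .process_sample(s, index, config), status = "ok",
                  reason = ""),
             error = function(e) list(outputs = character(0),
                                      status = "failed",
                                      reason = conditionMessage(e)))
  }
  results <- if (config$n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(samples), one, mc.cores = config$n_workers)
  } else lapply(seq_along(samples), one)
  rel_out <- function(paths) {
    if (!length(paths)) return("")
    paste(sort(.relative_to(paths, config$output_dir), method = "radix"),
          collapse = ";")
  }
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    patient_id = vapply(samples, `[[`, "", "patient_id"),
    members = vapply(samples, .sample_member_string, ""),
    outputs = vapply(results, function(r) rel_out(r$outputs), ""),
    status = vapply(results, `[[`, "", "status"),
    reason = vapply(results, `[[`, "", "reason"))
  n_failed <- sum(manifest$status == "failed")
  for (i in which(manifest$status == "failed"))
    log("sample ", manifest$sample_id[i], " failed: ", manifest$reason[i])
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest, file.path(config$output_dir, "manifest.csv"),
                   row.names = FALSE)
  pp <- config$processing
  jsonlite::write_json(list(
    tool = "rtcurate", tool_version = .rtcurate_version(),
    modalities = config$modalities, heuristic = config$heuristic,
    dedup = config$dedup,
    target_spacing = pp$target_spacing, window = pp$window,
    roi_patterns = pp$roi_patterns,
    roi_missing_policy = pp$roi_missing_policy,
    image_interp = pp$image_interp,
    index_checksum = .index_checksum(index)),
    file.path(config$output_dir, "run_info.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  if (config$nnunet)
    export_nnunet(config$output_dir, task = config$nnunet_task,
                  label_names = names(pp$roi_patterns),
                  overwrite_policy = config$overwrite_policy)
  tryCatch({
    logs_dir <- file.path(index_dir, "logs")
    dir.create(logs_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(log_lines, file.path(logs_dir, "run.log"))
  }, error = function(e) NULL)
  attr(manifest, "n_failed") <- n_failed
  invisible(manifest)
}

#' Export processed samples in nnU-Net dataset layout
#'
#' Re-arranges a pipeline output tree into the fixed layout consumed by
#' the nnU-Net segmentation framework:
#' `imagesTr/<task>_<case>_0000.nii.gz` and
#' `labelsTr/<task>_<case>.nii.gz` (case numbers `%04d`, following the
#' sorted sample order of the run manifest), plus `dataset.json` listing
#' the label names. The label volume combines the per-name binary masks of
#' each sample into one labelmap, later names overwriting earlier ones.
#'
#' @param output_dir a directory written by [run_pipeline()] (must contain
#'   `manifest.csv`).
#' @param task task name prefix.
#' @param label_names ordered character vector of mask output names; must
#'   be non-empty (checked before anything is written).
#' @param overwrite_policy as in [pipeline_config()]; `"skip_existing"`
#'   leaves already-exported case files untouched.
#' @return the nnU-Net root directory (`<output_dir>/nnunet`), invisibly.
#' @export
export_nnunet <- function(output_dir, task = "TASK", label_names,
                          overwrite_policy = "overwrite") {
  if (is.null(label_names) || length(label_names) == 0L)
    stop("empty label map: nnU-Net export requires named roi_patterns")
  mpath <- file.path(output_dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv under ", output_dir)
  manifest <- utils::read.csv(mpath, colClasses = "character")
  manifest <- manifest[manifest$status == "ok", , drop = FALSE]
  root <- file.path(output_dir, "nnunet")
  img_dir <- file.path(root, "imagesTr"); lab_dir <- file.path(root, "labelsTr")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  training <- list()
  for (i in seq_len(nrow(manifest))) {
    case <- sprintf("%s_%04d", task, i)
    outs <- strsplit(manifest$outputs[i], ";", fixed = TRUE)[[1]]
    img_src <- outs[basename(outs) %in% paste0(.image_modalities, ".nii.gz")][1]
    if (is.na(img_src)) stop("sample ", manifest$sample_id[i],
                             " has no image volume to export")
    img_dst <- file.path(img_dir, paste0(case, "_0000.nii.gz"))
    lab_dst <- file.path(lab_dir, paste0(case, ".nii.gz"))
    if (overwrite_policy == "skip_existing" && file.exists(img_dst) &&
        file.exists(lab_dst)) {
      training[[i]] <- list(image = file.path("imagesTr", basename(img_dst)),
                            label = file.path("labelsTr", basename(lab_dst)))
      next
    }
    file.copy(file.path(output_dir, img_src), img_dst, overwrite = TRUE)
    ref <- read_volume(file.path(output_dir, img_src))
    labels <- array(0L, dim(ref$voxels))
    for (li in seq_along(label_names)) {
      mp <- file.path(output_dir, dirname(img_src),
                      paste0("mask_", gsub("[^A-Za-z0-9_.-]", "_",
                                           label_names[li]), ".nii.gz"))
      if (!file.exists(mp)) stop("sample ", manifest$sample_id[i],
                                 " lacks mask for label '", label_names[li], "'")
      mv <- read_volume(mp)
      labels[mv$voxels != 0] <- li
    }
    lab_vol <- image_volume(labels, ref$origin, ref$spacing, ref$direction,
                            modality = "SEG", intensity_units = "label")
    write_volume(lab_vol, lab_dst, "nifti")
    training[[i]] <- list(image = file.path("imagesTr", basename(img_dst)),
                          label = file.path("labelsTr", basename(lab_dst)))
  }
  labels_json <- c(list(background = 0L),
                   stats::setNames(as.list(seq_along(label_names)), label_names))
  jsonlite::write_json(list(
    name = task, tensorImageSize = "3D",
    labels = stats::setNames(as.list(c("background", label_names)),
                             as.character(0:length(label_names))),
    numTraining = nrow(manifest), training = training),
    file.path(root, "dataset.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(root)
}
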