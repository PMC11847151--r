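# YAML configuration file support for the command-line pipeline. Precedence
# is CLI flag > config file > package default; the CLI applies flags on top
# of the list returned here.

#' Read pipeline settings from a YAML file
#'
#' Recognized keys mirror [pipeline_config()] and [processing_params()]:
#' `modalities`, `heuristic`, `spacing` (mm triple), `window`
#' (`[width, level]`), `roi_patterns` (map: label name -> list of
#' regexes), `roi_missing_policy`, `image_interp`, `workers`, `nnunet`,
#' `nnunet_task`, `overwrite_policy`, `dedup`.
#'
#' @param path YAML file.
#' @return a named list of settings (only the keys present in the file).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("modalities", "heuristic", "spacing", "window", "roi_patterns",
             "roi_missing_policy", "image_interp", "workers", "nnunet",
             "nnunet_task", "overwrite_policy", "dedup")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "))
  cfg
}

# Build a pipeline_config from merged CLI/file settings (internal, used by
# the command-line wrapper)
.pipeline_config_from_settings <- function(input_dir, output_dir, s) {
  processing <- processing_params(
    target_spacing = s$spacing,
    window = s$window,
    roi_patterns = s$roi_patterns,
    roi_missing_policy = s$roi_missing_policy %||% "warn",
    image_interp = s$image_interp %||% "linear")
  pipeline_config(
    input_dir = input_dir, output_dir = output_dir,
    modalities = s$modalities %||% "CT,RTSTRUCT",
    heuristic = s$heuristic %||% "metadata",
    processing = processing,
    n_workers = s$workers %||% 1L,
    nnunet = isTRUE(s$nnunet),
    nnunet_task = s$nnunet_task %||% "TASK",
    preloaded_index = s$preloaded_index,
    index_dir = s$index_dir,
    overwrite_policy = s$overwrite_policy %||% "error",
    dedup = s$dedup %||% "none")
}
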