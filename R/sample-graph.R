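# Stage 2, "connect": turn the series index into a directed reference graph
# and answer modality-combination queries. Edges point from the referencing
# series to the referenced one, so the DICOM-RT chain reads
# RTDOSE -> RTPLAN -> RTSTRUCT -> image. Every edge records how it was
# obtained (explicit_reference, frame_of_reference or study_fallback);
# fallback heuristics only ever add edges for series that have none, which
# makes the sample sets monotone across heuristics.

.image_modalities <- c("CT", "MR", "PT")
.supported_modalities <- c(.image_modalities, "RTSTRUCT", "RTPLAN", "RTDOSE")
.modality_rank <- c(CT = 0L, MR = 0L, PT = 0L, RTSTRUCT = 1L, RTPLAN = 2L,
                    RTDOSE = 3L)

#' Build the series reference graph
#'
#' Nodes are the series rows of the index. With `heuristic = "metadata"`
#' only explicit reference UIDs create edges (RTSTRUCT's referenced series,
#' RTDOSE's referenced plan, RTPLAN's referenced structure set). With
#' `"frame_of_reference"`, RT series still lacking an outgoing edge gain
#' edges to every image series of the same patient sharing their frame of
#' reference UID. With `"study"`, a final fallback links remaining
#' unconnected RT series to the image series of the same study. Each level
#' includes the previous one.
#'
#' @param index a `dataset_index`.
#' @param heuristic `"metadata"`, `"frame_of_reference"` or `"study"`.
#' @return an igraph with vertex attributes from the series table and an
#'   `edge_kind` edge attribute.
#' @export
build_graph <- function(index,
                        heuristic = c("metadata", "frame_of_reference", "study")) {
  heuristic <- match.arg(heuristic)
  s <- index$series
  g <- igraph::make_empty_graph(directed = TRUE)
  if (nrow(s) == 0L) return(g)
  g <- igraph::add_vertices(g, nrow(s),
    name = s$series_uid, patient_id = s$patient_id, study_uid = s$study_uid,
    modality = s$modality, frame_of_reference_uid = s$frame_of_reference_uid,
    series_date = s$series_date, n_files = s$n_files,
    file_paths = s$file_paths,
    has_reference = !is.na(s$referenced_series_uid) |
      !is.na(s$referenced_plan_uid) | !is.na(s$referenced_structset_uid))
  # SOP instance -> series lookup (plan/structset references are SOP UIDs)
  fr <- index$file_records
  sop2series <- stats::setNames(fr$series_uid, fr$sop_instance_uid)
  from <- character(0); to <- character(0); kind <- character(0)
  add_edge <- function(a, b, k) {
    from <<- c(from, a); to <<- c(to, b); kind <<- c(kind, k)
  }
  for (i in seq_len(nrow(s))) {
    tgt <- switch(s$modality[i],
      RTSTRUCT = s$referenced_series_uid[i],
      RTDOSE = unname(sop2series[s$referenced_plan_uid[i]]),
      RTPLAN = unname(sop2series[s$referenced_structset_uid[i]]),
      NA_character_)
    if (!is.na(tgt) && tgt %in% s$series_uid)
      add_edge(s$series_uid[i], tgt, "explicit_reference")
  }
  if (heuristic %in% c("frame_of_reference", "study")) {
    linked <- unique(from)
    for (i in seq_len(nrow(s))) {
      mod <- s$modality[i]
      if (mod %in% .image_modalities || s$series_uid[i] %in% linked) next
      if (is.na(s$frame_of_reference_uid[i])) next
      j <- which(s$modality %in% .image_modalities &
                 s$patient_id == s$patient_id[i] &
                 !is.na(s$frame_of_reference_uid) &
                 s$frame_of_reference_uid == s$frame_of_reference_uid[i])
      for (jj in j) add_edge(s$series_uid[i], s$series_uid[jj],
                             "frame_of_reference")
    }
  }
  if (heuristic == "study") {
    linked <- unique(from)
    for (i in seq_len(nrow(s))) {
      mod <- s$modality[i]
      if (mod %in% .image_modalities || s$series_uid[i] %in% linked) next
      j <- which(s$modality %in% .image_modalities &
                 s$patient_id == s$patient_id[i] &
                 s$study_uid == s$study_uid[i])
      for (jj in j) add_edge(s$series_uid[i], s$series_uid[jj],
                             "study_fallback")
    }
  }
  if (length(from))
    g <- igraph::add_edges(g, rbind(match(from, s$series_uid),
                                    match(to, s$series_uid)),
                           edge_kind = kind)
  g
}

.parse_modalities <- function(modalities) {
  toks <- toupper(trimws(strsplit(modalities, ",", fixed = TRUE)[[1]]))
  toks <- toks[nzchar(toks)]
  bad <- setdiff(toks, .supported_modalities)
  if (length(bad))
    stop("unknown modality token(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(.supported_modalities, collapse = ", "))
  unique(toks)
}

# stable short id from the sorted member series UIDs (md5 of their
# concatenation, first 10 hex chars)
.sample_id <- function(series_uids) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(sort(series_uids, method = "radix"), tf)
  substr(unname(tools::md5sum(tf)), 1L, 10L)
}

# walk every directed path from vertex v to an image series, collecting the
# series encountered; returns list of character vectors of vertex names
.chains_to_image <- function(g, v) {
  name <- igraph::V(g)$name[v]
  mod <- igraph::V(g)$modality[v]
  if (mod %in% .image_modalities) return(list(name))
  nxt <- igraph::neighbors(g, v, mode = "out")
  if (length(nxt) == 0L) return(list())
  out <- list()
  for (w in as.integer(nxt)) {
    for (tail in .chains_to_image(g, w))
      out[[length(out) + 1L]] <- c(name, tail)
  }
  out
}

#' Query coherent samples from the reference graph
#'
#' Returns one sample per maximal linked tuple of the requested
#' modalities, found by walking reference edges transitively: e.g.
#' `"CT,RTDOSE"` pairs a dose with the CT reached through its plan and
#' structure set even though neither intermediate is requested. A patient
#' with two structure sets on one CT yields two samples (explicit
#' cross-product policy; use `dedup = "latest"` to keep only the most
#' recent by series date).
#'
#' @param graph graph from [build_graph()].
#' @param modalities comma-separated modality tokens, e.g. `"CT,RTSTRUCT"`.
#' @param dedup `"none"` (all tuples) or `"latest"`.
#' @return list of `sample` objects: `patient_id`, `sample_id`, `members`
#'   (modality -> series row list), sorted by (patient_id, sample_id).
#' @export
query_samples <- function(graph, modalities, dedup = c("none", "latest")) {
  dedup <- match.arg(dedup)
  want <- .parse_modalities(modalities)
  if (igraph::vcount(graph) == 0L) return(list())
  vmod <- igraph::V(graph)$modality
  ranks <- .modality_rank[want]
  seed_mod <- want[which.max(ranks)]
  seeds <- which(vmod == seed_mod)
  samples <- list()
  for (v in seeds) {
    chains <- if (max(ranks) == 0L) list(igraph::V(graph)$name[v]) else
      .chains_to_image(graph, v)
    for (chain in chains) {
      ix <- match(chain, igraph::V(graph)$name)
      mods <- vmod[ix]
      keep <- mods %in% want
      if (!all(want %in% mods)) next
      member_ix <- ix[keep]
      pid <- unique(igraph::V(graph)$patient_id[member_ix])
      if (length(pid) != 1L) next # members must share one patient
      members <- lapply(member_ix, function(i) {
        list(series_uid = igraph::V(graph)$name[i],
             modality = vmod[i],
             patient_id = igraph::V(graph)$patient_id[i],
             study_uid = igraph::V(graph)$study_uid[i],
             series_date = igraph::V(graph)$series_date[i],
             file_paths = strsplit(igraph::V(graph)$file_paths[i], ";",
                                   fixed = TRUE)[[1]])
      })
      names(members) <- vmod[member_ix]
      members <- members[order(names(members), method = "radix")]
      sid <- .sample_id(vapply(members, `[[`, "", "series_uid"))
      samples[[sid]] <- structure(list(patient_id = pid, sample_id = sid,
                                       members = members), class = "sample")
    }
  }
  samples <- unname(samples)
  if (length(samples) == 0L) return(samples)
  ord <- order(vapply(samples, `[[`, "", "patient_id"),
               vapply(samples, `[[`, "", "sample_id"), method = "radix")
  samples <- samples[ord]
  if (dedup == "latest") {
    key <- vapply(samples, function(s)
      paste(s$patient_id, s$members[[1]]$series_uid), "")
    # keep, per (patient, anchor series), the sample with the latest
    # non-image series date; ties broken by sample_id order
    latest <- tapply(seq_along(samples), key, function(ix) {
      d <- vapply(samples[ix], function(s)
        max(vapply(s$members, `[[`, "", "series_date")), "")
      ix[which.max(d)]
    })
    samples <- samples[sort(unlist(latest))]
  }
  samples
}

#' @export
print.sample <- function(x, ...) {
  cat(sprintf("<sample %s> patient %s: %s\n", x$sample_id, x$patient_id,
              paste(names(x$members), collapse = " + ")))
  invisible(x)
}

#' Report queried series that joined no sample
#'
#' Lists every series of a queried modality that is absent from the
#' [query_samples()] result for the same query, with a reason:
#' `"no edge"` (the series carries no reference metadata and gained no
#' fallback edge) or `"missing partner"` (it has references or edges, but
#' no complete tuple with all queried modalities exists — e.g. an RTDOSE
#' whose referenced plan is absent from the dataset).
#'
#' @param graph graph from [build_graph()].
#' @param modalities comma-separated modality tokens.
#' @return a data.frame (zero rows when everything matched).
#' @export
report_unmatched <- function(graph, modalities) {
  want <- .parse_modalities(modalities)
  samples <- query_samples(graph, modalities)
  matched <- unlist(lapply(samples, function(s)
    vapply(s$members, `[[`, "", "series_uid")))
  out <- data.frame(series_uid = character(0), patient_id = character(0),
                    modality = character(0), reason = character(0))
  if (igraph::vcount(graph) == 0L) return(out)
  vmod <- igraph::V(graph)$modality
  for (v in seq_len(igraph::vcount(graph))) {
    if (!(vmod[v] %in% want)) next
    uid <- igraph::V(graph)$name[v]
    if (uid %in% matched) next
    has_out <- length(igraph::neighbors(graph, v, mode = "out")) > 0L
    has_in <- length(igraph::neighbors(graph, v, mode = "in")) > 0L
    has_ref <- isTRUE(igraph::V(graph)$has_reference[v])
    reason <- if (!vmod[v] %in% .image_modalities && !has_out && !has_ref)
        "no edge"
      else if (vmod[v] %in% .image_modalities && !has_in &&
               !setequal(want, vmod[v])) "no edge"
      else "missing partner"
    out <- rbind(out, data.frame(series_uid = uid,
                                 patient_id = igraph::V(graph)$patient_id[v],
                                 modality = vmod[v], reason = reason))
  }
  out[order(out$patient_id, out$series_uid, method = "radix"), , drop = FALSE]
}
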