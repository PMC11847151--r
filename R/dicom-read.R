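# DICOM Part-10 reader. Supports explicit and implicit VR little endian,
# nested sequences with defined or undefined lengths, and a metadata-only
# mode that seeks past PixelData (used by the crawler, which never needs
# voxel values).

.ru16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
.ru32 <- function(bytes, pos) {
  # as double: lengths can exceed .Machine$integer.max marker semantics
  sum(as.numeric(bytes[pos + 0:3]) * c(1, 256, 65536, 16777216))
}

.dcm_parse_string <- function(bytes, vr) {
  if (length(bytes) == 0L) return("")
  # strip trailing padding (space, or NUL for UI)
  while (length(bytes) > 0L && bytes[length(bytes)] %in% as.raw(c(0x00, 0x20)))
    bytes <- bytes[-length(bytes)]
  rawToChar(bytes)
}

.dcm_parse_value <- function(bytes, vr) {
  if (vr %in% .dcm_string_vrs) return(.dcm_parse_string(bytes, vr))
  switch(vr,
    DS = {
      s <- .dcm_parse_string(bytes, vr)
      if (!nzchar(s)) numeric(0) else as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
    },
    IS = {
      s <- .dcm_parse_string(bytes, vr)
      if (!nzchar(s)) integer(0) else as.integer(strsplit(s, "\\", fixed = TRUE)[[1]])
    },
    US = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = length(bytes) %/% 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = length(bytes) %/% 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) %/% 8L, size = 8L,
                 endian = "little"),
    bytes # OB / OW / UN: raw payload
  )
}

# Parse one dataset (sequence of elements) spanning bytes[pos..end].
# Returns list(elements = named list key "GGGGEEEE" -> list(vr, value),
#              pos = next position).
# stop_delim: if TRUE, stop (and consume) at an item delimitation tag.
.dcm_parse_dataset <- function(bytes, pos, end, explicit, read_pixel = TRUE,
                               stop_delim = FALSE, spans = FALSE) {
  out <- list()
  span_tab <- list()
  while (pos <= end) {
    start <- pos
    group <- .ru16(bytes, pos); elem <- .ru16(bytes, pos + 2L)
    pos <- pos + 4L
    if (group == 0xFFFEL && elem == 0xE00DL) { # item delimitation
      pos <- pos + 4L
      if (stop_delim) return(list(elements = out, pos = pos, spans = span_tab))
      next
    }
    key <- .dcm_tag_key(group, elem)
    if (explicit && group != 0xFFFEL) {
      vr <- rawToChar(bytes[pos + 0:1]); pos <- pos + 2L
      if (vr %in% .dcm_long_vrs) {
        len <- .ru32(bytes, pos + 2L); pos <- pos + 6L
      } else {
        len <- .ru16(bytes, pos); pos <- pos + 2L
      }
    } else {
      vr <- if (group == 0xFFFEL) "NA" else
        unname(.dcm_vr_by_key[key])
      if (is.na(vr)) vr <- "UN"
      len <- .ru32(bytes, pos); pos <- pos + 4L
    }
    undefined <- (len == 4294967295) # 0xFFFFFFFF
    if (vr == "SQ" || (undefined && group != 0x7FE0L)) {
      items <- list()
      if (undefined) {
        repeat {
          ig <- .ru16(bytes, pos); ie <- .ru16(bytes, pos + 2L)
          if (ig == 0xFFFEL && ie == 0xE0DDL) { pos <- pos + 8L; break }
          stopifnot(ig == 0xFFFEL, ie == 0xE000L)
          ilen <- .ru32(bytes, pos + 4L); pos <- pos + 8L
          if (ilen == 4294967295) {
            r <- .dcm_parse_dataset(bytes, pos, end, explicit, read_pixel,
                                    stop_delim = TRUE)
            items[[length(items) + 1L]] <- r$elements; pos <- r$pos
          } else {
            r <- .dcm_parse_dataset(bytes, pos, pos + ilen - 1L, explicit,
                                    read_pixel)
            items[[length(items) + 1L]] <- r$elements; pos <- pos + ilen
          }
        }
      } else {
        sq_end <- pos + len - 1L
        while (pos <= sq_end) {
          ig <- .ru16(bytes, pos); ie <- .ru16(bytes, pos + 2L)
          stopifnot(ig == 0xFFFEL, ie == 0xE000L)
          ilen <- .ru32(bytes, pos + 4L); pos <- pos + 8L
          if (ilen == 4294967295) {
            r <- .dcm_parse_dataset(bytes, pos, sq_end, explicit, read_pixel,
                                    stop_delim = TRUE)
            items[[length(items) + 1L]] <- r$elements; pos <- r$pos
          } else {
            r <- .dcm_parse_dataset(bytes, pos, pos + ilen - 1L, explicit,
                                    read_pixel)
            items[[length(items) + 1L]] <- r$elements; pos <- pos + ilen
          }
        }
      }
      out[[key]] <- list(vr = "SQ", value = items)
    } else {
      if (group == 0x7FE0L && elem == 0x0010L && !read_pixel) {
        out[[key]] <- list(vr = vr, value = NULL, skipped = TRUE)
      } else {
        if (len > 0 && pos + len - 1L > end)
          stop("truncated DICOM element (", key, "): declares ", len,
               " bytes but only ", end - pos + 1L, " remain")
        out[[key]] <- list(vr = vr,
                           value = .dcm_parse_value(bytes[pos + seq_len(len) - 1L], vr))
      }
      pos <- pos + len
    }
    if (spans) span_tab[[key]] <- c(start, pos - 1L)
  }
  list(elements = out, pos = pos, spans = span_tab)
}

#' Read a DICOM Part-10 file into a nested element list
#'
#' @param path file path.
#' @param read_pixel if `FALSE`, the PixelData payload is skipped (metadata
#'   crawl mode).
#' @return a list with `elements` (named by "GGGGEEEE" hex tag keys),
#'   `transfer_syntax`, and `path`; or `NULL` if the file carries no DICOM
#'   preamble/magic (the skip marker, distinguishable from an I/O error,
#'   which throws).
#' @noRd
dcm_read <- function(path, read_pixel = TRUE, spans = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  n <- file.size(path)
  if (is.na(n) || n < 140) return(NULL)
  bytes <- readBin(path, "raw", n = n)
  if (rawToChar(bytes[129:132]) != "DICM") return(NULL)
  pos <- 133L
  # file meta group: always explicit VR little endian
  meta <- list()
  while (pos <= n && .ru16(bytes, pos) == 0x0002L) {
    elem <- .ru16(bytes, pos + 2L)
    vr <- rawToChar(bytes[pos + 4:5])
    if (vr %in% .dcm_long_vrs) {
      len <- .ru32(bytes, pos + 8L); hdr <- 12L
    } else {
      len <- .ru16(bytes, pos + 6L); hdr <- 8L
    }
    key <- .dcm_tag_key(0x0002L, elem)
    meta[[key]] <- list(vr = vr,
                        value = .dcm_parse_value(bytes[pos + hdr + seq_len(len) - 1L], vr))
    pos <- pos + hdr + len
  }
  ts <- meta[[.dcm_dict$TransferSyntaxUID$key]]$value
  if (is.null(ts)) ts <- DCM_UID$ExplicitVRLittleEndian
  explicit <- !identical(ts, DCM_UID$ImplicitVRLittleEndian)
  body <- .dcm_parse_dataset(bytes, pos, n, explicit, read_pixel, spans = spans)
  list(elements = body$elements, meta = meta, transfer_syntax = ts,
       path = path, spans = body$spans, n_bytes = n)
}

# convenience accessors -------------------------------------------------

.dcm_get <- function(ds, name) {
  el <- ds$elements[[.dcm_dict[[name]]$key]]
  if (is.null(el)) NULL else el$value
}

.dcm_get_chr <- function(ds, name, default = NA_character_) {
  v <- .dcm_get(ds, name)
  if (is.null(v) || !length(v) || !nzchar(v[1])) default else v[1]
}

# Remove one top-level element from a DICOM file by byte splice, leaving all
# other bytes untouched. Returns TRUE if the tag was present and removed.
dcm_strip_tag <- function(path, name) {
  d <- .dcm_dict[[name]]
  ds <- dcm_read(path, read_pixel = FALSE, spans = TRUE)
  if (is.null(ds)) stop("not a DICOM file: ", path)
  span <- ds$spans[[d$key]]
  if (is.null(span)) return(FALSE)
  bytes <- readBin(path, "raw", n = ds$n_bytes)
  writeBin(bytes[-(span[1]:span[2])], path)
  TRUE
}
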