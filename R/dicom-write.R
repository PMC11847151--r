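# DICOM Part-10 writer (explicit VR little endian). Only the attributes in
# the package dictionary are writable; that covers CT image slices and the
# RT Structure Set / Plan / Dose objects the fixture generator emits.

.raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.raw_u32 <- function(x) {
  # writeBin() rejects values >= 2^31 for size-4 integers; lengths here are
  # always far below that, but keep the check explicit
  stopifnot(all(x >= 0), all(x < 2^31))
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

# Format a numeric as a DICOM decimal string (DS, max 16 bytes)
.dcm_format_ds <- function(x) {
  s <- sprintf("%.10g", x)
  if (any(nchar(s) > 16L)) s[nchar(s) > 16L] <- sprintf("%.8g", x[nchar(s) > 16L])
  s
}

#' @noRd
dcm_el <- function(name, value) {
  d <- .dcm_dict[[name]]
  if (is.null(d)) stop("unknown DICOM attribute name: ", name)
  list(group = d$group, elem = d$elem, vr = d$vr, value = value, name = name)
}

.dcm_encode_value <- function(vr, value) {
  if (vr %in% .dcm_string_vrs) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    return(b)
  }
  switch(vr,
    DS = {
      s <- paste(if (is.character(value)) value else .dcm_format_ds(value),
                 collapse = "\\")
      b <- charToRaw(s)
      if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))
      b
    },
    IS = {
      b <- charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\"))
      if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))
      b
    },
    US = .raw_u16(value),
    SS = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = .raw_u32(value),
    SL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4L, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
    OB = ,
    OW = as.raw(value),
    stop("unsupported VR for writing: ", vr)
  )
}

.dcm_encode_element <- function(el) {
  if (el$vr == "SQ") {
    body <- raw(0)
    for (item in el$value) {
      ib <- .dcm_encode_dataset(item)
      body <- c(body, .raw_u16(0xFFFEL), .raw_u16(0xE000L), .raw_u32(length(ib)), ib)
    }
  } else {
    body <- .dcm_encode_value(el$vr, el$value)
  }
  hdr <- c(.raw_u16(el$group), .raw_u16(el$elem), charToRaw(el$vr))
  if (el$vr %in% .dcm_long_vrs) {
    hdr <- c(hdr, as.raw(c(0L, 0L)), .raw_u32(length(body)))
  } else {
    if (length(body) > 0xFFFFL) stop("value too long for short-form VR ", el$vr)
    hdr <- c(hdr, .raw_u16(length(body)))
  }
  c(hdr, body)
}

.dcm_encode_dataset <- function(elements) {
  ord <- order(vapply(elements, function(e) e$group * 2^16 + e$elem, 0))
  do.call(c, lapply(elements[ord], .dcm_encode_element))
}

RTCURATE_IMPL_UID <- "1.2.826.0.1.3680043.9.7433.1.1"

#' Write a DICOM Part-10 file (explicit VR little endian)
#'
#' @param path output file path.
#' @param elements list of elements built with `dcm_el()`; must include
#'   SOPClassUID and SOPInstanceUID, which are mirrored into the file meta
#'   information group.
#' @return `path`, invisibly.
#' @noRd
dcm_write <- function(path, elements) {
  keys <- vapply(elements, function(e) .dcm_tag_key(e$group, e$elem), "")
  sop_class <- elements[[match(.dcm_dict$SOPClassUID$key, keys)]]$value
  sop_inst <- elements[[match(.dcm_dict$SOPInstanceUID$key, keys)]]$value
  meta <- list(
    dcm_el("FileMetaInformationVersion", as.raw(c(0L, 1L))),
    dcm_el("MediaStorageSOPClassUID", sop_class),
    dcm_el("MediaStorageSOPInstanceUID", sop_inst),
    dcm_el("TransferSyntaxUID", DCM_UID$ExplicitVRLittleEndian),
    dcm_el("ImplementationClassUID", RTCURATE_IMPL_UID)
  )
  meta_bytes <- .dcm_encode_dataset(meta)
  gl <- .dcm_encode_element(dcm_el("FileMetaInformationGroupLength",
                                   length(meta_bytes)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(gl, meta_bytes, .dcm_encode_dataset(elements)), con)
  invisible(path)
}
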