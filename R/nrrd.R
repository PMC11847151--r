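# Minimal NRRD codec: 3-D volumes, gzip encoding, LPS space. Header fields
# follow the NRRD0004 specification; space directions are the columns of
# direction %*% diag(spacing), i.e. the physical step per voxel index.

.nrrd_vec <- function(v) sprintf("(%s)", paste(sprintf("%.17g", v), collapse = ","))

.nrrd_type <- function(voxels) {
  v <- range(voxels)
  integral <- all(voxels == round(voxels))
  if (integral && v[1] >= 0 && v[2] <= 255) "uint8"
  else if (integral && v[1] >= -32768 && v[2] <= 32767) "short"
  else "double"
}

nrrd_write <- function(path, voxels, origin, spacing, direction) {
  type <- .nrrd_type(voxels)
  step <- direction %*% diag(spacing)
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(voxels), collapse = " ")),
    paste0("space directions: ", paste(apply(step, 2, .nrrd_vec), collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    paste0("space origin: ", .nrrd_vec(origin)),
    "", "")
  size <- switch(type, uint8 = 1L, short = 2L, double = 8L)
  what <- if (type == "double") as.numeric(voxels) else as.integer(voxels)
  payload <- writeBin(what, raw(), size = size, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste(hdr, collapse = "\n")), con)
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

nrrd_read <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line (\n\n)
  sep <- which(bytes[-length(bytes)] == as.raw(10L) & bytes[-1L] == as.raw(10L))[1]
  if (is.na(sep)) stop("malformed NRRD: no header terminator in ", path)
  lines <- strsplit(rawToChar(bytes[1:(sep - 1L)]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", lines[1])) stop("not a NRRD file: ", path)
  fields <- list()
  for (ln in lines[-1]) {
    if (grepl("^#", ln) || !nzchar(ln)) next
    kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
    fields[[kv[1]]] <- kv[2]
  }
  need <- c("type", "sizes", "encoding", "space directions", "space origin")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("NRRD header missing field(s): ", paste(miss, collapse = ", "))
  if (fields$encoding != "gzip") stop("unsupported NRRD encoding: ", fields$encoding)
  sizes <- as.integer(strsplit(fields$sizes, " ")[[1]])
  parse_vecs <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    vapply(m, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
  }
  step <- parse_vecs(fields$`space directions`) # 3x3, columns = axis steps
  origin <- as.numeric(parse_vecs(fields$`space origin`))
  spacing <- sqrt(colSums(step^2))
  direction <- step %*% diag(1 / spacing)
  payload <- memDecompress(bytes[(sep + 2L):length(bytes)], type = "gzip")
  n <- prod(sizes)
  voxels <- switch(fields$type,
    uint8 = as.numeric(readBin(payload, "integer", n = n, size = 1L, signed = FALSE)),
    short = as.numeric(readBin(payload, "integer", n = n, size = 2L,
                               signed = TRUE, endian = "little")),
    double = readBin(payload, "numeric", n = n, size = 8L, endian = "little"),
    stop("unsupported NRRD type: ", fields$type))
  dim(voxels) <- sizes
  list(voxels = voxels, origin = origin, spacing = spacing, direction = direction)
}
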