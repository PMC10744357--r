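# Minimal NRRD reader/writer for label volumes (attached header, raw or gzip
# encoding, little-endian). No installed R package reads NRRD, so the subset
# of the format needed for 3D integer label maps is implemented here.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed NRRD header (no blank terminator)")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(sub("^[^:]+:=?", "", line))
    fields[[key]] <- val
  }
  dims <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  ndim <- as.integer(fields[["dimension"]])
  if (ndim != 3L || length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  tinfo <- switch(type,
    "signed char" = , "int8" = , "int8_t" = list(what = "integer", size = 1L, signed = TRUE),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" = list(what = "integer", size = 1L, signed = FALSE),
    "short" = , "signed short" = , "int16" = , "int16_t" = list(what = "integer", size = 2L, signed = TRUE),
    "ushort" = , "unsigned short" = , "uint16" = , "uint16_t" = list(what = "integer", size = 2L, signed = FALSE),
    "int" = , "signed int" = , "int32" = , "int32_t" = list(what = "integer", size = 4L, signed = TRUE),
    stop("unsupported NRRD type: ", type))
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")
  n <- prod(dims)
  payload <- readBin(con, "raw", n = 1e9)
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = if (tinfo$size < 4L) tinfo$signed else TRUE,
                  endian = endian)
  if (length(vals) != n) stop("NRRD payload truncated: expected ", n, " values")
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    offdiag <- m - diag(diag(m))
    if (max(abs(offdiag)) > 1e-6 * max(abs(m)))
      stop("sheared/oblique NRRD space directions are not supported (grid must be axis-aligned)")
    spacing <- abs(diag(m))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- abs(as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]]))
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  list(data = array(as.integer(vals), dim = dims), spacing = spacing, origin = origin)
}

write_nrrd <- function(data, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- dim(data)
  stopifnot(length(dims) == 3L)
  hdr <- c("NRRD0004",
           "# written by femcurve",
           "type: int16",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(dims, collapse = " ")),
           paste0("space directions: (", spacing[1], ",0,0) (0,", spacing[2],
                  ",0) (0,0,", spacing[3], ")"),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: gzip",
           paste0("space origin: (", paste(origin, collapse = ","), ")"),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.integer(data), raw(), size = 2L, endian = "little")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}
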