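#' Read a triangulated surface mesh from disk
#'
#' Supports the FreeSurfer binary triangle-surface dialect (big-endian,
#' 3-byte magic `0xFFFFFE`), ASCII PLY and OFF. With `format = "auto"` the
#' format is sniffed from the file's leading bytes, falling back to the
#' file extension.
#'
#' Coordinates are taken to be millimetres (the FreeSurfer convention);
#' readers never rescale.
#'
#' @param path Path to the surface file.
#' @param format One of `"freesurfer"`, `"ply"`, `"off"`, `"auto"`.
#' @param name Mesh label; defaults to the file name.
#' @return A [surface_mesh].
#' @seealso [write_surface()]
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "ply", "off"),
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("surface file not found: ", path)
  if (is.null(name)) name <- basename(path)
  if (format == "auto") format <- sniff_surface_format(path)
  mesh <- switch(format,
    freesurfer = read_surface_freesurfer(path),
    ply = read_surface_ply(path),
    off = read_surface_off(path)
  )
  mesh$name <- name
  mesh
}

sniff_surface_format <- function(path) {
  head <- readBin(path, "raw", n = 16L)
  if (length(head) >= 3L &&
      head[1L] == as.raw(0xff) && head[2L] == as.raw(0xff) &&
      head[3L] == as.raw(0xfe)) return("freesurfer")
  txt <- rawToChar(head[head != as.raw(0)])
  if (startsWith(txt, "ply")) return("ply")
  if (startsWith(txt, "OFF")) return("off")
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = "ply", off = "off", "freesurfer")
}

#' Write a surface mesh to disk
#'
#' @param mesh A [surface_mesh].
#' @param path Output path.
#' @param format One of `"freesurfer"`, `"ply"`, `"off"`, or `"auto"`
#'   (from the extension; unknown extensions default to FreeSurfer).
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path,
                          format = c("auto", "freesurfer", "ply", "off")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", off = "off", "freesurfer")
  }
  switch(format,
    freesurfer = write_surface_freesurfer(mesh, path),
    ply = write_surface_ply(mesh, path),
    off = write_surface_off(mesh, path)
  )
  invisible(path)
}

## --- FreeSurfer binary triangle surface ------------------------------------

TRIANGLE_FILE_MAGIC <- c(0xff, 0xff, 0xfe)
CURV_FILE_MAGIC <- c(0xff, 0xff, 0xff)

read_surface_freesurfer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (length(magic) < 3L || !all(magic == as.raw(TRIANGLE_FILE_MAGIC)))
    stop("not a FreeSurfer triangle surface (bad magic at byte offset 0): ",
         path)
  # created-by comment: terminated by "\n\n"
  comment <- raw(0)
  prev_nl <- FALSE
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L)
      stop("truncated FreeSurfer surface header (unterminated comment, ",
           "byte offset ", 3L + length(comment), "): ", path)
    if (b == as.raw(0x0a)) {
      if (prev_nl) break
      prev_nl <- TRUE
    } else prev_nl <- FALSE
    comment <- c(comment, b)
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L))
    stop("malformed FreeSurfer surface counts record (byte offset ",
         3L + length(comment) + 1L, "): ", path)
  nv <- counts[1L]; nf <- counts[2L]
  if (nv == 0L) stop("empty mesh in ", path)
  v <- readBin(con, "double", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop("truncated FreeSurfer surface data: ", path)
  surface_mesh(matrix(v, ncol = 3L, byrow = TRUE),
               matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

write_surface_freesurfer <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(TRIANGLE_FILE_MAGIC), con)
  writeBin(charToRaw(sprintf("created by emod on %s\n\n",
                             format(Sys.time(), "%Y-%m-%d"))), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4L,
           endian = "big")
  writeBin(as.vector(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
}

## --- ASCII PLY --------------------------------------------------------------

read_surface_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop("not a PLY file (missing 'ply' magic): ", path)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("malformed PLY header (no end_header): ", path)
  hdr <- trimws(lines[seq_len(end_hdr)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", hdr, value = TRUE)[1L]))
  if (is.na(nv) || nv < 1L) stop("empty or malformed PLY vertex element: ", path)
  if (is.na(nf)) nf <- 0L
  body <- lines[(end_hdr + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vlines <- body[seq_len(nv)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(x)
    as.numeric(x[1:3])))
  f <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    flines <- body[nv + seq_len(nf)]
    f <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) {
      k <- as.integer(x[1L])
      if (k != 3L) stop("non-triangular PLY face (", k, " vertices): ", path)
      as.integer(x[2:4])
    }))
    f <- f + 1L
  }
  surface_mesh(v, f)
}

write_surface_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vtx <- apply(mesh$vertices, 1L, function(r)
    paste(sprintf("%.9g", r), collapse = " "))
  fac <- if (nf > 0L)
    apply(mesh$faces - 1L, 1L, function(r)
      paste(c("3", r), collapse = " ")) else character(0)
  writeLines(c(hdr, vtx, fac), path)
}

## --- OFF --------------------------------------------------------------------

read_surface_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L || lines[1L] != "OFF")
    stop("not an OFF file (missing 'OFF' magic): ", path)
  counts <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  if (is.na(nv) || nv < 1L) stop("empty or malformed OFF counts: ", path)
  v <- do.call(rbind, lapply(strsplit(lines[2L + seq_len(nv)], "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- matrix(integer(0), 0L, 3L)
  if (!is.na(nf) && nf > 0L) {
    f <- do.call(rbind,
                 lapply(strsplit(lines[2L + nv + seq_len(nf)], "\\s+"),
                        function(x) {
      k <- as.integer(x[1L])
      if (k != 3L) stop("non-triangular OFF face (", k, " vertices): ", path)
      as.integer(x[2:4])
    }))
    f <- f + 1L
  }
  surface_mesh(v, f)
}

write_surface_off <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  vtx <- apply(mesh$vertices, 1L, function(r)
    paste(sprintf("%.9g", r), collapse = " "))
  fac <- if (nf > 0L)
    apply(mesh$faces - 1L, 1L, function(r)
      paste(c("3", r), collapse = " ")) else character(0)
  writeLines(c("OFF", sprintf("%d %d 0", nv, nf), vtx, fac), path)
}

## --- Per-vertex scalar maps -------------------------------------------------

#' Read / write a per-vertex scalar map
#'
#' Supports the FreeSurfer "curv" new-format dialect (big-endian, 3-byte
#' magic `0xFFFFFF`, float32 values) and plain CSV with a single `value`
#' column. Curv round-trips within float32 precision; CSV round-trips
#' exactly as printed (17 significant digits). `NaN` entries are preserved
#' by both formats.
#'
#' @param path File path.
#' @param format `"curv"`, `"csv"`, or `"auto"` (sniffed / by extension).
#' @return Numeric vector of per-vertex values.
#' @export
read_vertex_map <- function(path, format = c("auto", "curv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("vertex map file not found: ", path)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 3L)
    format <- if (length(head) == 3L && all(head == as.raw(CURV_FILE_MAGIC)))
      "curv" else "csv"
  }
  if (format == "curv") {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", n = 3L)
    if (length(magic) < 3L || !all(magic == as.raw(CURV_FILE_MAGIC)))
      stop("not a new-format curv file (bad magic at byte offset 0): ", path)
    hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    vnum <- hdr[1L]
    if (hdr[3L] != 1L)
      stop("curv files with vals_per_vertex != 1 are not supported: ", path)
    vals <- readBin(con, "double", n = vnum, size = 4L, endian = "big")
    if (length(vals) < vnum) stop("truncated curv data: ", path)
    vals
  } else {
    df <- utils::read.csv(path)
    as.numeric(df[[1L]])
  }
}

#' @rdname read_vertex_map
#' @param map Numeric vector of per-vertex values.
#' @param mesh Optional [surface_mesh]; when given, `length(map)` must equal
#'   its vertex count (and the curv header records its face count).
#' @export
write_vertex_map <- function(map, path, format = c("auto", "curv", "csv"),
                             mesh = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else "curv"
  }
  map <- as.numeric(map)
  fnum <- 0L
  if (!is.null(mesh)) {
    if (length(map) != nrow(mesh$vertices))
      stop("map length (", length(map), ") does not match mesh vertex count (",
           nrow(mesh$vertices), ")")
    fnum <- nrow(mesh$faces)
  }
  if (format == "curv") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(CURV_FILE_MAGIC), con)
    writeBin(c(length(map), fnum, 1L), con, size = 4L, endian = "big")
    writeBin(map, con, size = 4L, endian = "big")
  } else {
    writeLines(c("value", sprintf("%.17g", map)), path)
  }
  invisible(path)
}
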