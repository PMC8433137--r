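#' STL mesh I/O
#'
#' Reads triangle meshes from ASCII or binary STL (auto-detected: a file is
#' treated as ASCII when it starts with `solid` and contains a `facet`
#' keyword). STL stores independent triangles, so identical vertices are
#' merged on read (exact coordinate match) to form an indexed mesh.
#'
#' @param path File path.
#' @param frame Frame to tag the mesh with (STL carries no frame metadata).
#' @return A [surface_model].
#' @export
read_stl <- function(path, frame = "PATIENT") {
  head_raw <- readBin(path, "raw", n = 512L)
  # byte-level detection: ASCII STL starts with "solid" and mentions "facet"
  is_ascii <- length(grepRaw("^\\s*solid", head_raw)) > 0L &&
    length(grepRaw("facet", head_raw)) > 0L
  tri <- if (is_ascii) .read_stl_ascii(path) else .read_stl_binary(path)
  if (nrow(tri) == 0L || nrow(tri) %% 3L != 0L) {
    nav_abort(sprintf("%s: no complete triangles found", path), "parse_error")
  }
  key <- apply(tri, 1L, paste, collapse = "\r")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_model(verts, faces, frame)
}

.read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(matrix(0, 0, 3))
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 4L)
  if (length(bad)) {
    nav_abort(sprintf("%s: malformed vertex line: '%s'", path, vl[bad[1]]),
              "parse_error")
  }
  t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
}

.read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)                       # header, ignored
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(n_tri) || n_tri < 0L) {
    nav_abort(sprintf("%s: invalid binary STL triangle count", path),
              "parse_error")
  }
  out <- matrix(NA_real_, n_tri * 3L, 3L)
  for (i in seq_len(n_tri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)                      # attribute byte count
    if (length(vals) < 12L) {
      nav_abort(sprintf("%s: truncated binary STL at triangle %d", path, i),
                "parse_error")
    }
    out[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  out
}

#' @rdname read_stl
#' @param surface A [surface_model] to write.
#' @param binary Write binary STL instead of ASCII.
#' @return `write_stl()` returns `path` invisibly.
#' @export
write_stl <- function(surface, path, binary = FALSE) {
  stopifnot(inherits(surface, "surface_model"))
  v <- surface$vertices
  f <- surface$faces
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      writeBin(c(0, 0, 0, as.numeric(t(tri))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- c("solid surface")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      out <- c(out, "  facet normal 0 0 0", "    outer loop",
               sprintf("      vertex %.17g %.17g %.17g",
                       tri[, 1], tri[, 2], tri[, 3]),
               "    endloop", "  endfacet")
    }
    writeLines(c(out, "endsolid surface"), path)
  }
  invisible(path)
}
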