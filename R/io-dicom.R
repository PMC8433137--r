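#' Read CT geometry from DICOM headers
#'
#' Header-only reader for the geometry attributes of a CT slice or series:
#' Image Position Patient (0020,0032), Image Orientation Patient (0020,0037)
#' and Pixel Spacing (0028,0030), plus Rows/Columns and, for a series, the
#' slice spacing measured as the distance between consecutive slice
#' positions along the slice normal (preferred over Slice Thickness
#' (0018,0050), which is unreliable for geometry). Pixel data are never
#' loaded. Only DICOM Part-10 files with the explicit-VR little-endian
#' transfer syntax are supported.
#'
#' @param path A single DICOM file, or a directory containing one series.
#' @param strict When the inter-slice spacing of a series varies by more
#'   than 1%, raise an error instead of a warning.
#' @return A [dicom_geometry]. For a single file, `slice_spacing` falls back
#'   to Slice Thickness (or 1 mm if absent, with a warning).
#' @export
read_dicom_geometry <- function(path, strict = FALSE) {
  files <- if (dir.exists(path)) {
    f <- list.files(path, full.names = TRUE)
    f[!dir.exists(f)]
  } else path
  if (!length(files)) {
    nav_abort(sprintf("no DICOM files found at %s", path), "input_error")
  }
  headers <- lapply(sort(files), .read_dicom_elements)
  first <- headers[[1L]]

  need <- c("0020,0032" = "Image Position Patient",
            "0020,0037" = "Image Orientation Patient",
            "0028,0030" = "Pixel Spacing",
            "0028,0010" = "Rows", "0028,0011" = "Columns")
  for (tag in names(need)) {
    if (is.null(first[[tag]])) {
      nav_abort(sprintf("DICOM header lacks tag (%s) %s", tag, need[[tag]]),
                "missing_tag_error")
    }
  }
  ipp <- first[["0020,0032"]]
  iop <- first[["0020,0037"]]
  ps <- first[["0028,0030"]]

  if (length(headers) > 1L) {
    normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
                iop[3] * iop[4] - iop[1] * iop[6],
                iop[1] * iop[5] - iop[2] * iop[4])
    pos <- vapply(headers, function(h) {
      p <- h[["0020,0032"]]
      if (is.null(p)) nav_abort("a series slice lacks tag (0020,0032)",
                                "missing_tag_error")
      sum(p * normal)
    }, numeric(1))
    ord <- order(pos)
    gaps <- diff(pos[ord])
    spacing <- mean(gaps)
    if (any(abs(gaps - spacing) > 0.01 * abs(spacing))) {
      msg <- sprintf("inconsistent slice spacing in series (%.4g to %.4g mm)",
                     min(gaps), max(gaps))
      if (strict) nav_abort(msg, "geometry_error") else
        nav_warn(msg, "geometry_warning")
    }
    ipp <- headers[[ord[1L]]][["0020,0032"]]
    n_slices <- length(headers)
  } else {
    spacing <- first[["0018,0050"]]
    if (is.null(spacing)) {
      nav_warn("single slice without Slice Thickness: assuming 1 mm spacing",
               "geometry_warning")
      spacing <- 1
    }
    n_slices <- 1L
  }
  dicom_geometry(ipp, iop, ps, spacing,
                 c(first[["0028,0010"]], first[["0028,0011"]], n_slices))
}

# Parse the data elements of one Part-10 explicit-VR little-endian file into
# a named list keyed "gggg,eeee". Values of numeric VRs are decoded; bulk
# VRs (incl. pixel data) are skipped without reading their bytes.
.read_dicom_elements <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132L)
  if (length(preamble) < 132L ||
      rawToChar(preamble[129:132]) != "DICM") {
    nav_abort(sprintf("%s is not a DICOM Part-10 file (no DICM marker)", path),
              "parse_error")
  }
  out <- list()
  repeat {
    ge <- readBin(con, "integer", n = 2L, size = 2L, signed = FALSE,
                  endian = "little")
    if (length(ge) < 2L) break
    vr <- rawToChar(readBin(con, "raw", n = 2L))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, "raw", n = 2L)
      len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    } else {
      len <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
                     endian = "little")
    }
    if (!length(len) || is.na(len) || len < 0L) break
    tag <- sprintf("%04x,%04x", ge[1], ge[2])
    if (tag == "7fe0,0010") break   # pixel data: never read
    val <- readBin(con, "raw", n = len)
    if (length(val) < len) break
    out[[tag]] <- switch(
      vr,
      DS = as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
      IS = as.integer(strsplit(trimws(rawToChar(val)), "\\\\")[[1]]),
      US = readBin(val, "integer", n = len %/% 2L, size = 2L,
                   signed = FALSE, endian = "little"),
      UL = readBin(val, "integer", n = len %/% 4L, size = 4L,
                   endian = "little"),
      FL = readBin(val, "numeric", n = len %/% 4L, size = 4L,
                   endian = "little"),
      FD = readBin(val, "numeric", n = len %/% 8L, size = 8L,
                   endian = "little"),
      trimws(rawToChar(val[val != as.raw(0)]))
    )
  }
  out
}

#' Write a synthetic DICOM header
#'
#' Emits a minimal DICOM Part-10 file (explicit VR little endian) carrying
#' only the geometry attributes, for building synthetic CT series in
#' simulations and tests; no pixel data are written. Not a clinical export.
#'
#' @param path Output file path.
#' @param ipp Image Position Patient (length 3, mm).
#' @param iop Image Orientation Patient (length 6).
#' @param pixel_spacing Length 2, mm.
#' @param rows,cols Matrix dimensions.
#' @param slice_thickness Optional Slice Thickness value, mm.
#' @return `path`, invisibly.
#' @export
write_dicom_header <- function(path, ipp, iop = c(1, 0, 0, 0, 1, 0),
                               pixel_spacing = c(0.5, 0.5),
                               rows = 512L, cols = 512L,
                               slice_thickness = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 128L)), con)
  writeBin(charToRaw("DICM"), con)
  wr <- function(group, elem, vr, raw_val) {
    writeBin(as.integer(c(group, elem)), con, size = 2L, endian = "little")
    writeBin(charToRaw(vr), con)
    if (length(raw_val) %% 2L) raw_val <- c(raw_val, charToRaw(" "))
    writeBin(as.integer(length(raw_val)), con, size = 2L, endian = "little")
    writeBin(raw_val, con)
  }
  ds <- function(x) charToRaw(paste(sprintf("%.10g", x), collapse = "\\"))
  us <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                             endian = "little")
  # file meta: transfer syntax (explicit VR little endian)
  wr(0x0002L, 0x0010L, "UI", charToRaw("1.2.840.10008.1.2.1"))
  wr(0x0008L, 0x0060L, "CS", charToRaw("CT"))
  if (!is.null(slice_thickness)) wr(0x0018L, 0x0050L, "DS", ds(slice_thickness))
  wr(0x0020L, 0x0032L, "DS", ds(ipp))
  wr(0x0020L, 0x0037L, "DS", ds(iop))
  wr(0x0028L, 0x0010L, "US", us(rows))
  wr(0x0028L, 0x0011L, "US", us(cols))
  wr(0x0028L, 0x0030L, "DS", ds(pixel_spacing))
  invisible(path)
}

#' Write a synthetic DICOM series
#'
#' Convenience wrapper around [write_dicom_header()] that writes one file
#' per slice with Image Position Patient stepped along the slice normal.
#'
#' @param dir Output directory (created if needed).
#' @param g A [dicom_geometry] describing the series.
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(dir, g) {
  stopifnot(inherits(g, "dicom_geometry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iop <- g$image_orientation_patient
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  for (k in seq_len(g$dimensions[3])) {
    write_dicom_header(
      file.path(dir, sprintf("slice%04d.dcm", k)),
      ipp = g$image_position_patient + (k - 1L) * g$slice_spacing * normal,
      iop = iop, pixel_spacing = g$pixel_spacing,
      rows = g$dimensions[1], cols = g$dimensions[2],
      slice_thickness = g$slice_spacing)
  }
  invisible(dir)
}
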