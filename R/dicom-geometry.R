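#' CT header geometry
#'
#' The subset of a DICOM CT header needed to build the voxel-to-patient map:
#' Image Position Patient (tag 0020,0032 of the first slice), Image
#' Orientation Patient (0020,0037), in-plane pixel spacing (0028,0030) and the
#' inter-slice spacing. Pixel data are never touched. Direction cosines must
#' be unit-norm and mutually orthogonal (tolerance 1e-6); spacings positive.
#'
#' @param image_position_patient Numeric length-3, mm (LPS): position of the
#'   first voxel's center of the first slice.
#' @param image_orientation_patient Numeric length-6: direction cosines of the
#'   row direction (first triplet = the column-index step direction X) and the
#'   column direction (second triplet = the row-index step direction Y).
#' @param pixel_spacing Numeric length-2, mm: (row spacing, column spacing) as
#'   in the DICOM attribute, i.e. spacing between rows then between columns.
#' @param slice_spacing Positive scalar, mm. Prefer the inter-slice distance
#'   of consecutive Image Position Patient values over Slice Thickness, which
#'   is unreliable for geometry.
#' @param dimensions Integer length-3: (rows, cols, slices).
#' @return Object of class `dicom_geometry`.
#' @export
#' @examples
#' g <- dicom_geometry(c(-100, -120, -50), c(1, 0, 0, 0, 1, 0),
#'                     c(0.5, 0.5), 0.6, c(512, 512, 300))
#' voxel_to_patient(g)
dicom_geometry <- function(image_position_patient,
                           image_orientation_patient,
                           pixel_spacing,
                           slice_spacing,
                           dimensions) {
  ipp <- as.numeric(image_position_patient)
  iop <- as.numeric(image_orientation_patient)
  ps <- as.numeric(pixel_spacing)
  stopifnot(length(ipp) == 3L, length(iop) == 6L, length(ps) == 2L,
            length(slice_spacing) == 1L, length(dimensions) == 3L)
  X <- iop[1:3]  # column-index (along a row) direction
  Y <- iop[4:6]  # row-index (down a column) direction
  tol <- 1e-6
  if (abs(sqrt(sum(X^2)) - 1) >= tol || abs(sqrt(sum(Y^2)) - 1) >= tol) {
    nav_abort("image orientation direction cosines are not unit-norm",
              "geometry_error")
  }
  if (abs(sum(X * Y)) >= tol) {
    nav_abort("image orientation direction cosines are not orthogonal",
              "geometry_error")
  }
  if (any(ps <= 0) || slice_spacing <= 0) {
    nav_abort("pixel and slice spacings must be positive", "geometry_error")
  }
  dims <- as.integer(dimensions)
  if (any(dims < 1L)) nav_abort("dimensions must be >= 1", "geometry_error")
  structure(
    list(image_position_patient = ipp,
         image_orientation_patient = iop,
         pixel_spacing = ps,
         slice_spacing = as.numeric(slice_spacing),
         dimensions = dims),
    class = "dicom_geometry"
  )
}

#' @export
print.dicom_geometry <- function(x, ...) {
  cat("<dicom_geometry>\n")
  cat("  IPP:", paste(format(x$image_position_patient), collapse = ", "), "\n")
  cat("  IOP:", paste(format(x$image_orientation_patient), collapse = ", "), "\n")
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm, dims %d x %d x %d\n",
              x$pixel_spacing[2], x$pixel_spacing[1], x$slice_spacing,
              x$dimensions[1], x$dimensions[2], x$dimensions[3]))
  invisible(x)
}

#' Voxel-to-patient affine map
#'
#' Builds the DICOM plane-equation affine mapping a 0-based voxel index
#' (col, row, slice) to LPS patient coordinates in mm:
#' `P = IPP + col * dcol * X + row * drow * Y + slice * dslice * (X x Y)`,
#' where X, Y are the Image Orientation Patient triplets. Voxel (0, 0, 0)
#' maps exactly to Image Position Patient. The result is affine
#' (`rigid = FALSE`) because of the anisotropic scaling.
#'
#' @param g A [dicom_geometry].
#' @return A `nav_transform` from `VOXEL` to `BL_IMAGE`.
#' @export
voxel_to_patient <- function(g) {
  stopifnot(inherits(g, "dicom_geometry"))
  X <- g$image_orientation_patient[1:3]
  Y <- g$image_orientation_patient[4:6]
  Z <- c(X[2] * Y[3] - X[3] * Y[2],
         X[3] * Y[1] - X[1] * Y[3],
         X[1] * Y[2] - X[2] * Y[1])
  m <- diag(4)
  m[1:3, 1] <- X * g$pixel_spacing[2]   # column index steps by column spacing
  m[1:3, 2] <- Y * g$pixel_spacing[1]   # row index steps by row spacing
  m[1:3, 3] <- Z * g$slice_spacing
  m[1:3, 4] <- g$image_position_patient
  new_transform(m, "VOXEL", "BL_IMAGE", rigid = FALSE)
}

#' Planning-to-navigation image-space transform
#'
#' Links the planning software's RAS image space to the navigation software's
#' DICOM LPS patient space. The planning frame is taken as the RAS mm space
#' anchored at the position of the first voxel, so the map is the RAS/LPS
#' flip followed by the Image Position Patient offset:
#' `p_BL = IPP + diag(-1, -1, 1) p_IPS`. With IPP = 0 this reduces to
#' [ras_lps_flip()]. The 3x3 block is a proper rotation, so the transform is
#' rigid. Sites whose planning software anchors its frame differently can
#' compose their own convention from [ras_lps_flip()], [voxel_to_patient()]
#' and [translation_transform()].
#'
#' @param g A [dicom_geometry].
#' @return A rigid `nav_transform` from `IPS_IMAGE` to `BL_IMAGE`.
#' @export
ips_to_bl <- function(g) {
  stopifnot(inherits(g, "dicom_geometry"))
  m <- diag(c(-1, -1, 1, 1))
  m[1:3, 4] <- g$image_position_patient
  new_transform(m, "IPS_IMAGE", "BL_IMAGE", rigid = TRUE)
}
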