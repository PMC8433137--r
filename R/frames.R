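#' Coordinate frames
#'
#' Every transform and landmark set in the package carries a frame tag, and
#' all algebra checks that frames chain before touching numbers. The built-in
#' vocabulary covers the spaces of a splint-based navigation workflow:
#'
#' * `PATIENT` — physical (tracker) space, mm.
#' * `DRF` — the dynamic reference frame rigidly attached to the patient
#'   (here: seated on the maxillary dentition via a splint), mm.
#' * `IPS_IMAGE` — planning-software image space, RAS orientation, mm.
#' * `BL_IMAGE` — navigation-software image space, DICOM LPS orientation, mm.
#' * `VOXEL` — 0-based voxel index space of the CT volume.
#'
#' User-defined frame names are permitted anywhere a frame is accepted; only
#' the built-in names carry a handedness attribute.
#'
#' @name frames
NULL

.FRAME_VOCAB <- c(
  PATIENT   = NA_character_,
  DRF       = NA_character_,
  IPS_IMAGE = "RAS",
  BL_IMAGE  = "LPS",
  VOXEL     = NA_character_
)

#' Known coordinate frame names
#'
#' @return Character vector of the built-in frame vocabulary.
#' @export
#' @examples
#' frame_vocabulary()
frame_vocabulary <- function() names(.FRAME_VOCAB)

#' Handedness convention of a frame
#'
#' @param frame Frame name (character scalar).
#' @return `"RAS"`, `"LPS"`, or `NA` for frames without a declared patient
#'   orientation (physical/tracker spaces, voxel indices, user frames).
#' @export
#' @examples
#' frame_handedness("IPS_IMAGE")
#' frame_handedness("BL_IMAGE")
frame_handedness <- function(frame) {
  stopifnot(is.character(frame), length(frame) == 1L)
  if (frame %in% names(.FRAME_VOCAB)) .FRAME_VOCAB[[frame]] else NA_character_
}

.check_frame <- function(frame, what = "frame") {
  if (!is.character(frame) || length(frame) != 1L || is.na(frame) ||
      !nzchar(frame)) {
    nav_abort(sprintf("%s must be a non-empty character scalar", what),
              "frame_error")
  }
  frame
}

# Classed conditions so callers/tests can dispatch on failure kind rather
# than on message text.
nav_abort <- function(message, class) {
  stop(structure(
    class = c(class, "regfreenav_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

nav_warn <- function(message, class) {
  warning(structure(
    class = c(class, "regfreenav_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

.check_frames_link <- function(have, need, context) {
  if (!identical(have, need)) {
    nav_abort(
      sprintf("frame chain broken in %s: have '%s', need '%s'",
              context, have, need),
      "frame_chain_error"
    )
  }
  invisible(TRUE)
}
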