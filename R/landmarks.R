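#' Labeled 3D landmark sets
#'
#' A `landmark_set` holds N uniquely labeled points (mm, or voxel indices when
#' the frame is `VOXEL`) in a declared coordinate frame. It is the container
#' for fiducials, targets, and acquired pointer coordinates.
#'
#' @param labels Character vector of unique labels.
#' @param coords Numeric N x 3 matrix (columns x, y, z).
#' @param frame Frame name; see [frames].
#' @return An object of class `landmark_set` with fields `labels`, `coords`
#'   (rownames set to the labels) and `frame`.
#' @export
#' @examples
#' landmark_set(c("nasion", "porion_L"),
#'              rbind(c(0, 25, 60), c(-55, -40, 35)), "PATIENT")
landmark_set <- function(labels, coords, frame) {
  labels <- as.character(labels)
  coords <- rbind(coords)
  storage.mode(coords) <- "double"
  if (length(labels) < 1L) {
    nav_abort("a landmark set needs at least one point", "landmark_error")
  }
  if (anyDuplicated(labels)) {
    nav_abort(sprintf("duplicate landmark labels: %s",
                      paste(unique(labels[duplicated(labels)]), collapse = ", ")),
              "landmark_error")
  }
  if (!is.matrix(coords) || ncol(coords) != 3L || nrow(coords) != length(labels)) {
    nav_abort("coords must be an N x 3 matrix matching the labels",
              "landmark_error")
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    nav_abort("landmark coordinates must be finite", "landmark_error")
  }
  .check_frame(frame)
  rownames(coords) <- labels
  colnames(coords) <- c("x", "y", "z")
  structure(list(labels = labels, coords = coords, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d point(s) in frame %s\n",
              length(x$labels), x$frame))
  print(round(x$coords, 4))
  invisible(x)
}

#' @export
as.data.frame.landmark_set <- function(x, ...) {
  data.frame(label = x$labels, x = x$coords[, 1], y = x$coords[, 2],
             z = x$coords[, 3], frame = x$frame,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subset a landmark set by label
#'
#' @param pts A [landmark_set].
#' @param labels Labels to keep, in the requested order.
#' @return A [landmark_set].
#' @export
subset_landmarks <- function(pts, labels) {
  stopifnot(inherits(pts, "landmark_set"))
  missing <- setdiff(labels, pts$labels)
  if (length(missing)) {
    nav_abort(sprintf("labels not present in landmark set: %s",
                      paste(missing, collapse = ", ")), "pairing_error")
  }
  landmark_set(labels, pts$coords[labels, , drop = FALSE], pts$frame)
}

# Reorder `other` to the label order of `ref`; both must carry identical
# label sets. Shared precondition of registration and TRE pairing.
.pair_landmarks <- function(ref, other, context) {
  if (!setequal(ref$labels, other$labels) ||
      length(ref$labels) != length(other$labels)) {
    nav_abort(sprintf("%s: landmark labels do not pair (%s vs %s)", context,
                      paste(ref$labels, collapse = ","),
                      paste(other$labels, collapse = ",")),
              "pairing_error")
  }
  subset_landmarks(other, ref$labels)
}
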