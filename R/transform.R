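#' Frame-tagged homogeneous transforms
#'
#' A `nav_transform` is a 4x4 homogeneous matrix mapping points from one named
#' frame to another, with an explicit rigidity flag. Rigid transforms must
#' have an orthonormal rotation block with determinant +1 (tolerance 1e-9);
#' affine transforms (e.g. the voxel-to-patient map) carry `rigid = FALSE`.
#' The last row is required to be exactly (0, 0, 0, 1).
#'
#' @param matrix Numeric 4x4 matrix; last row (0, 0, 0, 1).
#' @param from,to Frame names (character scalars); see [frames].
#' @param rigid Logical; if `TRUE` (default) the rotation block is validated
#'   for orthonormality and positive determinant.
#' @return An object of class `nav_transform`.
#' @seealso [compose()], [invert_transform()], [apply_transform()]
#' @export
#' @examples
#' t1 <- translation_transform(c(1, 2, 3), "PATIENT", "BL_IMAGE")
#' t1$matrix
new_transform <- function(matrix, from, to, rigid = TRUE) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(4L, 4L)) ||
      !is.numeric(matrix)) {
    nav_abort("transform matrix must be a numeric 4x4 matrix",
              "transform_error")
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    nav_abort("transform matrix contains non-finite entries", "transform_error")
  }
  if (!identical(unname(matrix[4L, ]), c(0, 0, 0, 1))) {
    nav_abort("transform last row must be exactly (0, 0, 0, 1)",
              "transform_error")
  }
  .check_frame(from, "from frame")
  .check_frame(to, "to frame")
  stopifnot(is.logical(rigid), length(rigid) == 1L, !is.na(rigid))
  if (rigid) .check_rigid_block(matrix[1:3, 1:3, drop = FALSE])
  structure(
    list(matrix = unname(matrix), from = from, to = to, rigid = rigid),
    class = "nav_transform"
  )
}

.RIGID_TOL <- 1e-9

.check_rigid_block <- function(R, tol = .RIGID_TOL) {
  dev <- max(abs(crossprod(R) - diag(3)))
  d <- det(R)
  if (dev >= tol || abs(d - 1) >= tol) {
    nav_abort(
      sprintf(paste0("rotation block is not rigid: ",
                     "max |R'R - I| = %.3g, det = %.12f"), dev, d),
      "rigidity_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.nav_transform <- function(x, ...) {
  cat(sprintf("<nav_transform> %s -> %s (%s)\n", x$from, x$to,
              if (x$rigid) "rigid" else "affine"))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity transform
#'
#' @param from Frame name; also used as the target frame unless `to` differs.
#' @param to Target frame name (defaults to `from`; an identity matrix between
#'   distinct frames expresses coincident frames).
#' @return A rigid `nav_transform`.
#' @export
identity_transform <- function(from, to = from) {
  new_transform(diag(4), from, to, rigid = TRUE)
}

#' Pure translation transform
#'
#' @param offset Numeric length-3 translation, mm.
#' @inheritParams identity_transform
#' @return A rigid `nav_transform`.
#' @export
translation_transform <- function(offset, from, to = from) {
  stopifnot(is.numeric(offset), length(offset) == 3L)
  m <- diag(4)
  m[1:3, 4] <- offset
  new_transform(m, from, to, rigid = TRUE)
}

#' Rigid transform from Euler angles and a translation
#'
#' Rotation is applied as Rz(yaw) Ry(pitch) Rx(roll) about the origin,
#' followed by the translation. Angles in degrees.
#'
#' @param angles_deg Numeric length-3: (roll x, pitch y, yaw z), degrees.
#' @param offset Numeric length-3 translation, mm.
#' @inheritParams identity_transform
#' @return A rigid `nav_transform`.
#' @export
#' @examples
#' rz90 <- euler_transform(c(0, 0, 90), c(0, 0, 0), "PATIENT")
#' apply_transform(rz90, landmark_set("p", matrix(c(1, 0, 0), 1), "PATIENT"))
euler_transform <- function(angles_deg, offset = c(0, 0, 0), from, to = from) {
  stopifnot(is.numeric(angles_deg), length(angles_deg) == 3L,
            is.numeric(offset), length(offset) == 3L)
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  m <- diag(4)
  m[1:3, 1:3] <- Rz %*% Ry %*% Rx
  m[1:3, 4] <- offset
  new_transform(m, from, to, rigid = TRUE)
}

#' Compose two transforms
#'
#' `compose(a, b)` maps `a$from` to `b$to` by applying `a` first, then `b`
#' (matrix product `b$matrix %*% a$matrix`). The frames must chain:
#' `a$to == b$from`.
#'
#' @param a,b `nav_transform` objects.
#' @return A `nav_transform`; rigid iff both inputs are rigid.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "nav_transform"), inherits(b, "nav_transform"))
  .check_frames_link(a$to, b$from, "compose(a, b)")
  out <- new_transform(b$matrix %*% a$matrix, a$from, b$to,
                       rigid = a$rigid && b$rigid)
  out
}

#' Invert a transform
#'
#' For rigid transforms the inverse is computed in closed form as
#' (R^T, -R^T t) rather than by generic matrix inversion; affine transforms
#' are inverted with [solve()].
#'
#' @param t A `nav_transform`.
#' @return The inverse `nav_transform` with from/to frames swapped.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "nav_transform"))
  m <- diag(4)
  if (t$rigid) {
    R <- t$matrix[1:3, 1:3, drop = FALSE]
    m[1:3, 1:3] <- t(R)
    m[1:3, 4] <- -t(R) %*% t$matrix[1:3, 4]
  } else {
    A <- t$matrix[1:3, 1:3, drop = FALSE]
    if (abs(det(A)) < 1e-12) {
      nav_abort("transform is singular and cannot be inverted",
                "degenerate_transform_error")
    }
    Ai <- solve(A)
    m[1:3, 1:3] <- Ai
    m[1:3, 4] <- -Ai %*% t$matrix[1:3, 4]
  }
  new_transform(m, t$to, t$from, rigid = t$rigid)
}

#' Apply a transform to a landmark set
#'
#' Points are treated as homogeneous with w = 1. The landmark frame must
#' equal the transform's source frame; the result is tagged with the target
#' frame and keeps the labels.
#'
#' @param t A `nav_transform`.
#' @param pts A [landmark_set].
#' @return A [landmark_set] in frame `t$to`.
#' @export
apply_transform <- function(t, pts) {
  stopifnot(inherits(t, "nav_transform"), inherits(pts, "landmark_set"))
  .check_frames_link(pts$frame, t$from, "apply_transform(t, pts)")
  landmark_set(pts$labels, apply_transform_xyz(t, pts$coords), t$to)
}

# Matrix-level worker: n x 3 in, n x 3 out. Used internally where frame
# bookkeeping has already been done.
apply_transform_xyz <- function(t, xyz) {
  xyz <- rbind(xyz) # tolerate a bare length-3 vector
  out <- xyz %*% t(t$matrix[1:3, 1:3, drop = FALSE])
  sweep(out, 2L, -t$matrix[1:3, 4])
}

#' RAS/LPS patient-orientation flip
#'
#' The involutory map diag(-1, -1, 1) on (x, y, z) converting between
#' right-anterior-superior and left-posterior-superior patient coordinates.
#' As a 3x3 block this is a proper rotation (180 degrees about z), so the
#' transform is rigid. Applying it twice is the identity.
#'
#' @param from,to Frame names; defaults map planning (RAS) image space to
#'   navigation (LPS) image space.
#' @return A rigid `nav_transform`.
#' @export
ras_lps_flip <- function(from = "IPS_IMAGE", to = "BL_IMAGE") {
  m <- diag(c(-1, -1, 1, 1))
  new_transform(m, from, to, rigid = TRUE)
}
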