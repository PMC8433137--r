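#' Splint-borne DRF design
#'
#' The pre-operative design artifacts of registration-free navigation: the
#' pose of the dynamic reference frame (DRF) on the splint expressed in the
#' planning software's image space, the splint geometry (used for its
#' centroid, the origin of the distance covariate in the accuracy analysis),
#' and optionally the DRF's marker/sensor geometry in the DRF frame.
#'
#' @param drf_pose_ips Rigid `nav_transform` from `DRF` to `IPS_IMAGE`: the
#'   designed pose of the splint-borne DRF in planning image space.
#' @param splint_vertices Numeric N x 3 matrix of splint surface/outline
#'   points in `IPS_IMAGE`, mm.
#' @param drf_marker_geometry Optional [landmark_set] of marker sphere or
#'   sensor positions in the `DRF` frame.
#' @return Object of class `splint_design`.
#' @export
splint_design <- function(drf_pose_ips, splint_vertices,
                          drf_marker_geometry = NULL) {
  stopifnot(inherits(drf_pose_ips, "nav_transform"))
  if (!drf_pose_ips$rigid) {
    nav_abort("the DRF pose must be rigid", "rigidity_error")
  }
  .check_frames_link(drf_pose_ips$from, "DRF", "splint_design")
  .check_frames_link(drf_pose_ips$to, "IPS_IMAGE", "splint_design")
  splint_vertices <- rbind(splint_vertices)
  storage.mode(splint_vertices) <- "double"
  if (nrow(splint_vertices) < 1L || ncol(splint_vertices) != 3L ||
      anyNA(splint_vertices)) {
    nav_abort("splint_vertices must be a non-empty finite N x 3 matrix",
              "input_error")
  }
  if (!is.null(drf_marker_geometry)) {
    stopifnot(inherits(drf_marker_geometry, "landmark_set"))
  }
  structure(list(drf_pose_ips = drf_pose_ips,
                 splint_vertices = unname(splint_vertices),
                 drf_marker_geometry = drf_marker_geometry),
            class = "splint_design")
}

#' Splint centroid
#'
#' Arithmetic mean of the splint vertices; the anchor from which target
#' distances are measured in the accuracy analysis.
#'
#' @param design A [splint_design].
#' @return Numeric length-3, mm, in `IPS_IMAGE`.
#' @export
splint_centroid <- function(design) {
  stopifnot(inherits(design, "splint_design"))
  colMeans(design$splint_vertices)
}

#' Build the registration-free transform chain
#'
#' Composes the pre-operatively known DRF pose in planning image space
#' (T from splint/DRF to planning image) with the planning-to-navigation
#' image-space transform derived from the CT header to obtain the DRF pose
#' in navigation image space. That composed transform links patient space
#' and image space once the splint is seated, so it substitutes for an
#' intra-operatively measured registration.
#'
#' @param design A [splint_design].
#' @param g A [dicom_geometry] of the navigation CT volume.
#' @return Object of class `regfree_chain` with fields `t_spl_ips`,
#'   `t_ips_bl`, and the derived `t_spl_bl = compose(t_spl_ips, t_ips_bl)`.
#' @export
build_chain <- function(design, g) {
  stopifnot(inherits(design, "splint_design"), inherits(g, "dicom_geometry"))
  t_spl_ips <- design$drf_pose_ips
  t_ips_bl <- ips_to_bl(g)
  structure(list(t_spl_ips = t_spl_ips,
                 t_ips_bl = t_ips_bl,
                 t_spl_bl = compose(t_spl_ips, t_ips_bl)),
            class = "regfree_chain")
}

#' @export
print.regfree_chain <- function(x, ...) {
  cat("<regfree_chain> DRF -> IPS_IMAGE -> BL_IMAGE\n")
  print(x$t_spl_bl)
  invisible(x)
}

#' Undo a pre-registration
#'
#' The navigation system requires some registration before it will acquire
#' coordinates, so a temporary pre-registration is performed and later
#' corrected. This function removes it: acquired image-space coordinates are
#' mapped back through the rigid inverse of the recorded pre-registration,
#' yielding the acquisitions expressed relative to the DRF. (The correction
#' is the rigid inverse `(R^T, -R^T t)`; for a pure rotation this coincides
#' with the matrix transpose.)
#'
#' @param c_acquired [landmark_set] of acquired coordinates in the
#'   pre-registration's image frame.
#' @param t_reg Rigid `nav_transform` from `DRF` to that image frame: the
#'   recorded pre-registration.
#' @return [landmark_set] `c'` in the `DRF` frame.
#' @export
correct_preregistration <- function(c_acquired, t_reg) {
  stopifnot(inherits(c_acquired, "landmark_set"),
            inherits(t_reg, "nav_transform"))
  if (!t_reg$rigid) {
    nav_abort("the pre-registration must be rigid to be corrected",
              "rigidity_error")
  }
  apply_transform(invert_transform(t_reg), c_acquired)
}

#' Recalculate acquisitions into image space
#'
#' Maps DRF-relative acquisitions through the registration-free chain's
#' DRF-to-navigation-image transform, producing the coordinates the workflow
#' reports in image space (`c''`). Together with
#' [correct_preregistration()] this realizes the recalculation
#' `c'' = T_chain * inv(T_prereg) * c`, which is independent of whatever
#' pre-registration was used.
#'
#' @param c_prime [landmark_set] in the `DRF` frame.
#' @param chain A `regfree_chain` from [build_chain()].
#' @return [landmark_set] `c''` in `BL_IMAGE`.
#' @export
to_image_space <- function(c_prime, chain) {
  stopifnot(inherits(c_prime, "landmark_set"), inherits(chain, "regfree_chain"))
  apply_transform(chain$t_spl_bl, c_prime)
}

#' Target registration error
#'
#' Per-target Euclidean distance (mm) between measured and true landmark
#' positions, both in the same image frame.
#'
#' @param c_final [landmark_set] of measured positions.
#' @param targets [landmark_set] of true target positions; labels must pair
#'   with `c_final`.
#' @return Named non-negative numeric vector of distances, mm, in the label
#'   order of `c_final`.
#' @export
#' @examples
#' a <- landmark_set("t", matrix(c(0, 0, 0), 1), "BL_IMAGE")
#' b <- landmark_set("t", matrix(c(3, 4, 0), 1), "BL_IMAGE")
#' tre(a, b)  # 5
tre <- function(c_final, targets) {
  stopifnot(inherits(c_final, "landmark_set"), inherits(targets, "landmark_set"))
  .check_frames_link(targets$frame, c_final$frame, "tre")
  targets <- .pair_landmarks(c_final, targets, "tre")
  d <- sqrt(rowSums((c_final$coords - targets$coords)^2))
  names(d) <- c_final$labels
  d
}
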