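#' Rigid point-based (fiducial) registration
#'
#' Closed-form least-squares rigid registration of paired, labeled fiducials:
#' finds the rigid transform minimizing the sum of squared distances
#' `sum ||T m_i - f_i||^2` via the SVD of the cross-covariance matrix, with
#' determinant correction so the rotation is always proper (det R = +1, no
#' reflection, even for mirrored inputs). This is the operation a navigation
#' system performs when the surgeon indicates bone-anchored fiducial screws.
#'
#' @param moving [landmark_set] of localized fiducials (e.g. physical/tracker
#'   space).
#' @param fixed [landmark_set] of the corresponding fiducials in the target
#'   frame (e.g. image space). Labels must pair with `moving`.
#' @return A `registration_result`: list with `transform` (moving frame to
#'   fixed frame), `fre_mm` (root-mean-square fiducial residual),
#'   `n_points_used`, `converged`, `iterations` (1 for the closed form).
#' @export
#' @examples
#' m <- landmark_set(letters[1:4],
#'                   rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10)),
#'                   "PATIENT")
#' f <- apply_transform(euler_transform(c(0, 0, 90), c(5, 0, 0),
#'                                      "PATIENT", "BL_IMAGE"), m)
#' register_point_based(m, f)$fre_mm
register_point_based <- function(moving, fixed) {
  stopifnot(inherits(moving, "landmark_set"), inherits(fixed, "landmark_set"))
  fixed <- .pair_landmarks(moving, fixed, "register_point_based")
  n <- length(moving$labels)
  if (n < 3L) {
    nav_abort("point-based registration needs at least 3 fiducials",
              "configuration_error")
  }
  s <- svd(scale(moving$coords, center = TRUE, scale = FALSE))$d
  if (s[2] <= 1e-6 * s[1]) {
    nav_abort("fiducial configuration is collinear (or a single point)",
              "configuration_error")
  }
  fit <- .kabsch(moving$coords, fixed$coords)
  m <- diag(4)
  m[1:3, 1:3] <- fit$R
  m[1:3, 4] <- fit$t
  tr <- new_transform(m, moving$frame, fixed$frame, rigid = TRUE)
  res <- apply_transform_xyz(tr, moving$coords) - fixed$coords
  new_registration_result(
    transform = tr,
    fre_mm = sqrt(mean(rowSums(res^2))),
    n_points_used = n,
    converged = TRUE,
    iterations = 1L
  )
}

# Kabsch/Horn closed form: R, t minimizing sum ||R m_i + t - f_i||^2,
# reflection excluded by the sign correction on the smallest singular value.
.kabsch <- function(M, F) {
  mbar <- colMeans(M); fbar <- colMeans(F)
  Mc <- sweep(M, 2L, mbar); Fc <- sweep(F, 2L, fbar)
  s <- svd(crossprod(Mc, Fc))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(fbar - R %*% mbar))
}

new_registration_result <- function(transform, fre_mm, n_points_used,
                                    converged, iterations, rms_trace = NULL) {
  structure(list(transform = transform, fre_mm = fre_mm,
                 n_points_used = n_points_used, converged = converged,
                 iterations = iterations, rms_trace = rms_trace),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %s -> %s | FRE %.4f mm | %d point(s), %d iter, %s\n",
    x$transform$from, x$transform$to, x$fre_mm, x$n_points_used, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fiducial registration error
#'
#' Root-mean-square of the post-transform fiducial residuals
#' `||T m_i - f_i||`. Evaluated on the fitting data this equals the
#' `fre_mm` reported by [register_point_based()]; it may be evaluated on any
#' paired landmark sets (e.g. held-out fiducials).
#'
#' @param result A `registration_result` (or bare `nav_transform`).
#' @param moving,fixed Paired [landmark_set]s as in [register_point_based()].
#' @return Non-negative RMS residual in mm.
#' @export
fre <- function(result, moving, fixed) {
  tr <- if (inherits(result, "registration_result")) result$transform else result
  stopifnot(inherits(tr, "nav_transform"))
  fixed <- .pair_landmarks(moving, fixed, "fre")
  .check_frames_link(moving$frame, tr$from, "fre")
  .check_frames_link(fixed$frame, tr$to, "fre")
  res <- apply_transform_xyz(tr, moving$coords) - fixed$coords
  sqrt(mean(rowSums(res^2)))
}

#' Surface-based registration (iterative closest point)
#'
#' Point-to-surface ICP: in each iteration every probe point is matched to
#' its closest point on the mesh (closest point on a triangle, not nearest
#' vertex) and the rigid update is re-fit from the original probe points to
#' the matched correspondences with the closed-form solver. Iteration stops
#' when the RMS correspondence distance decreases by less than `tol` or at
#' `max_iterations`; non-convergence is reported in the result, not raised.
#' This is the generic stand-in for a navigation system's proprietary
#' soft-tissue (skin-surface) registration.
#'
#' @param probe_points [landmark_set] of at least 10 points acquired on the
#'   physical surface (e.g. skin), in the moving frame.
#' @param surface [surface_model] in the target (image) frame.
#' @param init `nav_transform` initial guess linking the probe frame to the
#'   surface frame; ICP is local, so a coarse initial pose is required.
#' @param max_iterations Iteration cap (default 200).
#' @param tol RMS-change stopping threshold in mm (default 1e-6).
#' @param trim_fraction Fraction of worst-matched points ignored in each
#'   rigid update (default 0 = plain ICP).
#' @return A `registration_result`; `fre_mm` is the final RMS point-to-surface
#'   distance and `rms_trace` the per-iteration RMS (non-increasing).
#' @export
register_surface <- function(probe_points, surface, init,
                             max_iterations = 200L, tol = 1e-6,
                             trim_fraction = 0) {
  stopifnot(inherits(probe_points, "landmark_set"),
            inherits(surface, "surface_model"),
            inherits(init, "nav_transform"))
  if (length(probe_points$labels) < 10L) {
    nav_abort("surface registration needs at least 10 probe points",
              "input_error")
  }
  .check_frames_link(probe_points$frame, init$from, "register_surface")
  .check_frames_link(init$to, surface$frame, "register_surface")
  stopifnot(trim_fraction >= 0, trim_fraction < 1)

  p0 <- probe_points$coords
  n_keep <- max(3L, ceiling((1 - trim_fraction) * nrow(p0)))
  cur <- init
  rms_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    moved <- apply_transform_xyz(cur, p0)
    cp <- closest_point_on_mesh(moved, surface)
    keep <- order(cp$distance)[seq_len(n_keep)]
    rms <- sqrt(mean(cp$distance[keep]^2))
    rms_trace <- c(rms_trace, rms)
    if (it > 1L && abs(rms_trace[it - 1L] - rms) < tol) {
      converged <- TRUE
      break
    }
    fit <- .kabsch(p0[keep, , drop = FALSE], cp$points[keep, , drop = FALSE])
    m <- diag(4)
    m[1:3, 1:3] <- fit$R
    m[1:3, 4] <- fit$t
    cur <- new_transform(m, probe_points$frame, surface$frame, rigid = TRUE)
  }
  new_registration_result(
    transform = cur,
    fre_mm = rms_trace[length(rms_trace)],
    n_points_used = n_keep,
    converged = converged,
    iterations = it,
    rms_trace = rms_trace
  )
}
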