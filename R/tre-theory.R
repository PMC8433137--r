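#' First-order expected TRE of point-based registration
#'
#' Closed-form root-mean-square target registration error expected after
#' rigid point-based registration of N fiducials with isotropic fiducial
#' localization error:
#'
#' \deqn{E[TRE^2(r)] = \frac{FLE^2}{N}\left(1 + \frac{1}{3}\sum_{k=1}^3
#'   \frac{d_k^2}{f_k^2}\right)}
#'
#' where \eqn{d_k} is the distance of the target from the k-th principal axis
#' of the fiducial configuration and \eqn{f_k} the RMS distance of the
#' fiducials from that axis. The formula is the standard first-order
#' propagation result for fiducial-based registration; it explains why a
#' nearly coplanar fiducial patch (small \eqn{f_k} along one axis) produces
#' TRE that grows with target distance from the fiducial centroid. Used here
#' as the analytic oracle the Monte-Carlo simulator is checked against.
#'
#' @param fiducials [landmark_set] of at least 3 non-collinear fiducials.
#' @param target Numeric length-3 point, an N x 3 matrix, or a
#'   [landmark_set]; same frame as the fiducials.
#' @param fle_rms Root-mean-square 3D fiducial localization error, mm (for
#'   isotropic per-axis SD sigma this is `sqrt(3) * sigma`).
#' @return Expected RMS TRE in mm (vector if multiple targets).
#' @export
#' @examples
#' fid <- landmark_set(paste0("f", 1:4),
#'                     rbind(c(-20, 0, 0), c(20, 0, 0),
#'                           c(0, -15, 1), c(0, 15, -1)), "PATIENT")
#' predict_tre_point_based(fid, c(0, 0, 100), fle_rms = 0.5)
predict_tre_point_based <- function(fiducials, target, fle_rms) {
  stopifnot(inherits(fiducials, "landmark_set"),
            is.numeric(fle_rms), length(fle_rms) == 1L, fle_rms >= 0)
  n <- length(fiducials$labels)
  if (n < 3L) {
    nav_abort("TRE prediction needs at least 3 fiducials",
              "configuration_error")
  }
  X <- scale(fiducials$coords, center = TRUE, scale = FALSE)
  sv <- svd(X)
  if (sv$d[2] <= 1e-6 * sv$d[1]) {
    nav_abort("fiducial configuration is collinear", "configuration_error")
  }
  if (inherits(target, "landmark_set")) target <- target$coords
  target <- rbind(target)
  stopifnot(ncol(target) == 3L)
  centroid <- attr(X, "scaled:center")
  V <- sv$v                       # principal axis directions
  # squared distance from axis k = |y|^2 - (y . v_k)^2
  Tc <- sweep(target, 2L, centroid)
  t_norm2 <- rowSums(Tc^2)
  proj2 <- (Tc %*% V)^2
  d2 <- t_norm2 - proj2           # n_targets x 3
  f2 <- (sum(sv$d^2) - sv$d^2) / n  # mean squared fiducial distance per axis
  # guard: a coplanar configuration has f_3 > 0 only through its jitter;
  # exactly-zero spread along an axis makes the first-order term infinite
  if (any(f2 <= 0)) {
    nav_abort("fiducial configuration is degenerate along a principal axis",
              "configuration_error")
  }
  as.numeric(fle_rms * sqrt((1 + rowSums(sweep(d2, 2L, f2, "/")) / 3) / n))
}
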