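# Shared generators for the test suite. Everything is built in code at test
# time; tests that need randomness set their own seed first.

random_rigid <- function(from = "PATIENT", to = "BL_IMAGE",
                         max_angle = 180, max_trans = 100) {
  euler_transform(stats::runif(3, -max_angle, max_angle),
                  stats::runif(3, -max_trans, max_trans), from, to)
}

random_landmarks <- function(n, frame = "PATIENT", spread = 50) {
  landmark_set(paste0("p", seq_len(n)),
               matrix(stats::runif(n * 3, -spread, spread), n, 3), frame)
}

rot_z <- function(angle_deg, frame = "PATIENT") {
  euler_transform(c(0, 0, angle_deg), c(0, 0, 0), frame)
}

# Independent numerical oracle for rigid point-based registration: direct
# minimization of the RMS residual by multistart simplex search over the
# rotation vector (Rodrigues axis-angle), with the translation profiled out
# (for any fixed rotation the least-squares translation aligns the
# centroids). Deliberately ignorant of the closed form it checks.
brute_force_registration_rms <- function(moving, fixed) {
  rodrigues <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    k <- w / th
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  Mc <- scale(moving$coords, scale = FALSE)
  Fc <- scale(fixed$coords, scale = FALSE)
  n <- nrow(Mc)
  obj <- function(w) sqrt(sum((Fc - Mc %*% t(rodrigues(w)))^2) / n)
  starts <- rbind(c(0, 0, 0), pi * diag(3), -pi * diag(3),
                  matrix(stats::runif(12, -pi, pi), 4, 3))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-15))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Angle (deg) and translation norm (mm) separating two rigid transforms.
pose_delta <- function(a, b) {
  d <- a$matrix %*% solve(b$matrix)
  ang <- acos(min(1, max(-1, (sum(diag(d[1:3, 1:3])) - 1) / 2))) * 180 / pi
  list(angle_deg = ang, trans_mm = sqrt(sum(d[1:3, 4]^2)))
}

zero_noise <- function() noise_model(0, 0, 0, 0, 0, 0)

# Contrast vectors expressing each group line as a linear combination of
# fixed-effect terms, aligned to `terms` and to the derive_group_lines()
# row order (optical/bone, optical/rf, EM/bone, EM/surface, EM/rf).
group_line_contrasts <- function(terms) {
  w <- function(...) {
    v <- stats::setNames(numeric(length(terms)), terms)
    v[c(...)] <- 1
    v
  }
  list(
    intercept = rbind(
      w("intercept"),
      w("intercept", "method_registration_free"),
      w("intercept", "technique_em"),
      w("intercept", "technique_em", "method_surface_based"),
      w("intercept", "technique_em", "method_registration_free",
        "technique_em_x_method_registration_free")),
    slope = rbind(
      w("distance"),
      w("distance", "distance_x_method_registration_free"),
      w("distance", "distance_x_technique_em"),
      w("distance", "distance_x_technique_em",
        "distance_x_method_surface_based"),
      w("distance", "distance_x_technique_em",
        "distance_x_method_registration_free",
        "distance_x_technique_em_x_method_registration_free")))
}

# matrix-level application of a homogeneous 4x4 to n x 3 coordinates
apply_transform_q <- function(q4, coords) {
  t(q4[1:3, 1:3] %*% t(coords) + q4[1:3, 4])
}
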