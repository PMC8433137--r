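test_that("point-based registration recovers exact rigid correspondence", {
  m <- landmark_set(paste0("f", 1:5),
                    rbind(c(0, 0, 0), c(30, 0, 0), c(0, 25, 0),
                          c(0, 0, 20), c(15, 10, 8)), "PATIENT")
  r0 <- register_point_based(m, landmark_set(m$labels, m$coords, "PATIENT"))
  expect_equal(r0$transform$matrix, diag(4), tolerance = 1e-12)
  expect_equal(r0$fre_mm, 0, tolerance = 1e-12)
  expect_identical(r0$iterations, 1L)

  truth <- euler_transform(c(0, 0, 90), c(5, 0, 0), "PATIENT", "BL_IMAGE")
  f <- apply_transform(truth, m)
  r <- register_point_based(m, f)
  expect_lt(max(abs(r$transform$matrix - truth$matrix)), 1e-9)
  expect_lt(r$fre_mm, 1e-9)
  expect_equal(det(r$transform$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
})

test_that("degenerate fiducial configurations are rejected", {
  two <- landmark_set(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0)), "PATIENT")
  expect_error(register_point_based(two, two), class = "configuration_error")

  line <- landmark_set(paste0("l", 1:4),
                       cbind(1:4, 2 * (1:4), -1 * (1:4)), "PATIENT")
  expect_error(register_point_based(line, line),
               class = "configuration_error")

  a <- random_landmarks(4)
  b <- landmark_set(paste0("q", 1:4), a$coords, "BL_IMAGE")
  expect_error(register_point_based(a, b), class = "pairing_error")
})

test_that("fre matches its definition and is label-order invariant", {
  set.seed(21)
  m <- random_landmarks(5)
  truth <- random_rigid("PATIENT", "BL_IMAGE", max_angle = 40, max_trans = 20)
  f <- apply_transform(truth, m)
  # displace one fiducial by 1 mm: RMS residual of the identity-fit is known
  f_pert <- landmark_set(f$labels, f$coords + rbind(c(1, 0, 0), matrix(0, 4, 3)),
                         "BL_IMAGE")
  expect_equal(fre(truth, m, f_pert), sqrt(1 / 5), tolerance = 1e-12)
  expect_equal(fre(truth, m, f_pert),
               fre(truth, subset_landmarks(m, rev(m$labels)),
                   subset_landmarks(f_pert, rev(f_pert$labels))))
  r <- register_point_based(m, f_pert)
  expect_equal(fre(r, m, f_pert), r$fre_mm, tolerance = 1e-12)
})

test_that("closed form matches a brute-force minimizer and never reflects", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    m <- random_landmarks(n, spread = 40)
    truth <- random_rigid("PATIENT", "BL_IMAGE")
    f <- apply_transform(truth, m)
    f <- landmark_set(f$labels, f$coords + matrix(rnorm(n * 3, 0, 1), n, 3),
                      "BL_IMAGE")
    r <- register_point_based(m, f)
    expect_equal(det(r$transform$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
    oracle <- brute_force_registration_rms(m, f)
    expect_lt(abs(r$fre_mm - oracle), 1e-6)
  }
})

test_that("mirrored correspondences yield the best proper rotation", {
  set.seed(32)
  m <- random_landmarks(6, spread = 30)
  mirrored <- landmark_set(m$labels, m$coords %*% diag(c(-1, 1, 1)),
                           "BL_IMAGE")
  r <- register_point_based(m, mirrored)
  expect_equal(det(r$transform$matrix[1:3, 1:3]), 1, tolerance = 1e-9)
  expect_lt(abs(r$fre_mm - brute_force_registration_rms(m, mirrored)), 1e-6)
})

test_that("registration is rotation-equivariant", {
  set.seed(33)
  m <- random_landmarks(6)
  f <- apply_transform(random_rigid("PATIENT", "PATIENT", 30, 10), m)
  f <- landmark_set(f$labels, f$coords + matrix(rnorm(18, 0, 0.5), 6, 3),
                    "PATIENT")
  base <- register_point_based(m, f)$transform$matrix
  q <- rot_z(54)$matrix
  mq <- landmark_set(m$labels, apply_transform_q(q, m$coords), "PATIENT")
  fq <- landmark_set(f$labels, apply_transform_q(q, f$coords), "PATIENT")
  conj <- register_point_based(mq, fq)$transform$matrix
  expect_lt(max(abs(conj - q %*% base %*% solve(q))), 1e-8)
})

test_that("ICP is a fixed point on exact data and descends monotonically", {
  ph <- make_phantom(5)
  set.seed(51)
  probe <- sample_mesh_points(ph$skin_surface_patient, 30)
  r <- register_surface(probe, ph$skin_surface, ph$true_ct_pose)
  expect_true(r$converged)
  expect_lt(r$fre_mm, 1e-6)
  expect_lt(max(abs(r$transform$matrix - ph$true_ct_pose$matrix)), 1e-9)

  # perturbed start with noisy points: residual trace never increases
  noisy <- landmark_set(probe$labels,
                        probe$coords + matrix(rnorm(90, 0, 0.5), ncol = 3),
                        "PATIENT")
  init <- compose(euler_transform(c(2, -1, 3), c(2, 2, -1),
                                  "PATIENT", "PATIENT"), ph$true_ct_pose)
  r2 <- register_surface(noisy, ph$skin_surface, init, max_iterations = 60)
  expect_true(all(diff(r2$rms_trace) <= 1e-12))
})

test_that("ICP recovers a small rigid motion from exact surface samples", {
  ph <- make_phantom(3)
  set.seed(54)
  probe <- sample_mesh_points(ph$skin_surface_patient, 60)
  # start up to ~5 degrees / 3 mm away from the true pose
  init <- compose(euler_transform(c(3, -4, 2), c(2, -2, 1),
                                  "PATIENT", "PATIENT"), ph$true_ct_pose)
  r <- register_surface(probe, ph$skin_surface, init, max_iterations = 1200L,
                        tol = 1e-9)
  delta <- pose_delta(r$transform, ph$true_ct_pose)
  expect_lt(delta$trans_mm, 0.1)
  expect_lt(delta$angle_deg, 0.1)
  expect_lt(r$fre_mm, 0.05)
})

test_that("ICP result does not depend on mesh face ordering", {
  ph <- make_phantom(6)
  set.seed(52)
  probe <- sample_mesh_points(ph$skin_surface_patient, 25)
  noisy <- landmark_set(probe$labels,
                        probe$coords + matrix(rnorm(75, 0, 0.4), ncol = 3),
                        "PATIENT")
  init <- compose(euler_transform(c(1, 2, -2), c(1, -1, 2),
                                  "PATIENT", "PATIENT"), ph$true_ct_pose)
  r1 <- register_surface(noisy, ph$skin_surface, init, max_iterations = 40)
  perm <- rev(seq_len(nrow(ph$skin_surface$faces)))
  shuffled <- surface_model(ph$skin_surface$vertices,
                            ph$skin_surface$faces[perm, ], "BL_IMAGE")
  r2 <- register_surface(noisy, shuffled, init, max_iterations = 40)
  expect_lt(max(abs(r1$transform$matrix - r2$transform$matrix)), 1e-9)
})

test_that("ICP input validation and non-convergence reporting", {
  ph <- make_phantom(7)
  set.seed(53)
  few <- sample_mesh_points(ph$skin_surface_patient, 5)
  expect_error(register_surface(few, ph$skin_surface, ph$true_ct_pose),
               class = "input_error")

  probe <- sample_mesh_points(ph$skin_surface_patient, 15)
  noisy <- landmark_set(probe$labels,
                        probe$coords + matrix(rnorm(45, 0, 1), ncol = 3),
                        "PATIENT")
  init <- compose(euler_transform(c(4, -3, 2), c(3, 3, -2),
                                  "PATIENT", "PATIENT"), ph$true_ct_pose)
  r <- register_surface(noisy, ph$skin_surface, init, max_iterations = 3L)
  expect_false(r$converged)
  expect_identical(r$iterations, 3L)
})
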