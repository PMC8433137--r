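test_that("phantom generation is deterministic and anatomically plausible", {
  a <- make_phantom(17)
  b <- make_phantom(17)
  expect_identical(a$targets$coords, b$targets$coords)
  expect_identical(a$fiducials$coords, b$fiducials$coords)
  expect_identical(a$true_ct_pose$matrix, b$true_ct_pose$matrix)
  expect_false(identical(make_phantom(18)$targets$coords, a$targets$coords))

  expect_length(a$fiducials$labels, 5L)
  expect_length(a$targets$labels, 14L)
  expect_setequal(a$targets$labels, target_vocabulary())

  # near-coplanar fiducial patch: smallest principal-axis SD well under 5 mm
  pc_sd <- sqrt(stats::prcomp(a$fiducials$coords)$sdev^2)
  expect_lt(min(pc_sd), 5)
  # target lever arms span the short-to-long range of the cranium
  d <- target_distances(a)
  expect_gt(min(d), 30); expect_lt(min(d), 60)
  expect_gt(max(d), 140); expect_lt(max(d), 200)
})

test_that("sessions are reproducible and validate the design pairing", {
  ph <- make_phantom(19)
  nz <- noise_model()
  s1 <- simulate_session(ph, "EM", "bone_anchored", nz, seed = 5)
  s2 <- simulate_session(ph, "EM", "bone_anchored", nz, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_session(ph, "EM", "bone_anchored", nz, seed = 6)
  expect_false(identical(s1$tre_mm, s3$tre_mm))

  expect_error(simulate_session(ph, "optical", "surface_based", nz, 1),
               class = "design_error")
})

test_that("zero noise gives zero TRE in every arm", {
  ph <- make_phantom(20)
  arms <- list(c("optical", "bone_anchored"), c("optical", "registration_free"),
               c("EM", "bone_anchored"), c("EM", "surface_based"),
               c("EM", "registration_free"))
  for (arm in arms) {
    s <- simulate_session(ph, arm[1], arm[2], zero_noise(), seed = 77)
    expect_lt(max(s$tre_mm), 1e-9)
  }
})

test_that("registration-free records are invariant to the pre-registration", {
  ph <- make_phantom(21)
  p1 <- euler_transform(c(10, 20, 30), c(5, -5, 9), "DRF", "BL_IMAGE")
  p2 <- euler_transform(c(-50, 12, 170), c(99, 0, -40), "DRF", "BL_IMAGE")
  s1 <- simulate_session(ph, "EM", "registration_free", noise_model(),
                         seed = 7, prereg = p1)
  s2 <- simulate_session(ph, "EM", "registration_free", noise_model(),
                         seed = 7, prereg = p2)
  expect_equal(s1$x, s2$x, tolerance = 1e-10)
  expect_equal(s1$y, s2$y, tolerance = 1e-10)
  expect_equal(s1$z, s2$z, tolerance = 1e-10)
  expect_equal(s1$tre_mm, s2$tre_mm, tolerance = 1e-10)
})

test_that("study bookkeeping equals the factorial product minus missing", {
  des <- study_design(
    methods_by_technique = list(optical = "bone_anchored",
                                EM = c("bone_anchored", "registration_free")),
    n_observers = 2L, n_repetitions = 2L, n_cadavers = 2L,
    missing_records = c(3L, 50L, 111L))
  study <- simulate_study(des, phantom_seeds = 1L, zero_noise())
  expect_identical(nrow(study), 3L * 2L * 2L * 2L * 14L - 3L)
  expect_false(any(c(3L, 50L, 111L) %in% study$row_id))

  des0 <- study_design(
    methods_by_technique = list(optical = "bone_anchored",
                                EM = "registration_free"),
    n_observers = 1L, n_repetitions = 1L, n_cadavers = 1L,
    missing_records = integer(0))
  expect_identical(nrow(simulate_study(des0, 1L, zero_noise())), 28L)
})

test_that("study generation is seed-deterministic and order-stable", {
  des <- study_design(
    methods_by_technique = list(optical = "bone_anchored",
                                EM = "bone_anchored"),
    n_observers = 2L, n_repetitions = 2L, n_cadavers = 2L,
    missing_records = integer(0))
  a <- simulate_study(des, phantom_seeds = 9L, noise_model())
  b <- simulate_study(des, phantom_seeds = 9L, noise_model())
  expect_identical(a$tre_mm, b$tre_mm)
  # observer substreams differ: repeated metadata cells are not clones
  cell1 <- a$tre_mm[a$observer == 1 & a$technique == "EM" & a$repetition == 1]
  cell2 <- a$tre_mm[a$observer == 2 & a$technique == "EM" & a$repetition == 1]
  expect_false(isTRUE(all.equal(cell1, cell2)))
})

test_that("first-order TRE prediction has the right structure", {
  fid <- landmark_set(paste0("f", 1:5),
                      rbind(c(-20, 24, 10), c(-10, 40, 12), c(0, 46, 9),
                            c(10, 40, 11), c(20, 24, 10)), "PATIENT")
  expect_equal(predict_tre_point_based(fid, c(0, 0, 100), 0), 0)
  centroid <- colMeans(fid$coords)
  expect_equal(predict_tre_point_based(fid, centroid, 0.5), 0.5 / sqrt(5),
               tolerance = 1e-12)
  # minimum at the centroid
  expect_gt(predict_tre_point_based(fid, centroid + c(30, 0, 5), 0.5),
            predict_tre_point_based(fid, centroid, 0.5))
  line <- landmark_set(paste0("l", 1:4), cbind(1:4, 2 * (1:4), 3 * (1:4)),
                       "PATIENT")
  expect_error(predict_tre_point_based(line, c(0, 0, 0), 0.3),
               class = "configuration_error")
})

test_that("group-line generator reproduces its inputs exactly at zero noise", {
  gl <- data.frame(
    technique = c("optical", "optical", "EM", "EM", "EM"),
    method = c("bone_anchored", "registration_free", "bone_anchored",
               "surface_based", "registration_free"),
    intercept = c(0.97, 1.16, 0.91, 1.10, 0.84),
    slope = c(0.0049, 0.0039, 0.0042, 0.0013, 0.0036))
  des <- study_design(n_observers = 1L, n_repetitions = 1L, n_cadavers = 2L,
                      missing_records = integer(0))
  recs <- simulate_from_group_lines(gl, des, make_phantom(1), cadaver_sd = 0,
                                    residual_sd = 0, seed = 3)
  expect_identical(nrow(recs), 5L * 2L * 14L)
  key <- paste(recs$technique, recs$method)
  gi <- match(key, paste(gl$technique, gl$method))
  expect_equal(recs$sqrt_tre,
               gl$intercept[gi] + gl$slope[gi] * recs$centered_distance_mm,
               tolerance = 1e-12)
  expect_equal(recs$tre_mm, recs$sqrt_tre^2, tolerance = 1e-12)
})
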