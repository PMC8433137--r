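test_that("compose chains frames and matrices correctly", {
  t1 <- random_rigid("PATIENT", "DRF")
  expect_equal(compose(identity_transform("PATIENT"), t1)$matrix, t1$matrix)
  rt <- compose(t1, invert_transform(t1))
  expect_lt(max(abs(rt$matrix - diag(4))), 1e-12)
  expect_identical(rt$from, "PATIENT")
  expect_identical(rt$to, "PATIENT")

  # two quarter turns about z send (1, 0, 0) to (-1, 0, 0)
  half <- compose(rot_z(90), rot_z(90))
  p <- apply_transform(half, landmark_set("p", matrix(c(1, 0, 0), 1), "PATIENT"))
  expect_equal(unname(p$coords[1, ]), c(-1, 0, 0), tolerance = 1e-12)

  expect_error(compose(random_rigid("PATIENT", "DRF"),
                       random_rigid("BL_IMAGE", "IPS_IMAGE")),
               class = "frame_chain_error")
  # the error names both frames involved
  err <- tryCatch(compose(random_rigid("PATIENT", "DRF"),
                          random_rigid("BL_IMAGE", "IPS_IMAGE")),
                  error = identity)
  expect_match(conditionMessage(err), "DRF")
  expect_match(conditionMessage(err), "BL_IMAGE")
})

test_that("invert is the exact rigid inverse and swaps frames", {
  ti <- invert_transform(translation_transform(c(1, 2, 3), "PATIENT"))
  expect_equal(ti$matrix[1:3, 4], c(-1, -2, -3))
  expect_equal(invert_transform(identity_transform("DRF"))$matrix, diag(4))

  set.seed(41)
  for (i in 1:20) {
    tr <- random_rigid()
    pts <- random_landmarks(6)
    back <- apply_transform(invert_transform(tr), apply_transform(tr, pts))
    expect_lt(max(abs(back$coords - pts$coords)), 1e-10)
    expect_identical(back$frame, "PATIENT")
  }
})

test_that("rigid transforms are closed under compose/invert and are isometries", {
  set.seed(42)
  for (i in 1:15) {
    a <- random_rigid("PATIENT", "DRF")
    b <- random_rigid("DRF", "BL_IMAGE")
    ab <- compose(a, b)           # constructor re-validates rigidity
    expect_true(ab$rigid)
    expect_true(invert_transform(ab)$rigid)

    pts <- random_landmarks(8)
    moved <- apply_transform(ab, pts)
    expect_lt(max(abs(dist(moved$coords) - dist(pts$coords))), 1e-9)
  }
})

test_that("non-rigid matrices are rejected when flagged rigid", {
  m <- diag(c(2, 1, 1, 1))
  expect_error(new_transform(m, "PATIENT", "DRF", rigid = TRUE),
               class = "rigidity_error")
  # reflection has det -1: not a rigid body motion
  expect_error(new_transform(diag(c(-1, 1, 1, 1)), "PATIENT", "DRF",
                             rigid = TRUE),
               class = "rigidity_error")
  expect_silent(new_transform(m, "VOXEL", "BL_IMAGE", rigid = FALSE))
})

test_that("RAS/LPS flip is the involutory axis flip and an isometry", {
  fl <- ras_lps_flip()
  p <- apply_transform(fl, landmark_set("p", matrix(c(1, 2, 3), 1),
                                        "IPS_IMAGE"))
  expect_equal(unname(p$coords[1, ]), c(-1, -2, 3))
  expect_identical(p$frame, "BL_IMAGE")

  twice <- compose(fl, ras_lps_flip("BL_IMAGE", "IPS_IMAGE"))
  expect_equal(twice$matrix, diag(4))

  set.seed(7)
  pts <- random_landmarks(10, frame = "IPS_IMAGE")
  expect_equal(as.numeric(dist(apply_transform(fl, pts)$coords)),
               as.numeric(dist(pts$coords)), tolerance = 1e-12)
})

test_that("voxel_to_patient follows the DICOM plane equation", {
  g <- dicom_geometry(c(-100, -120, -50), c(1, 0, 0, 0, 1, 0),
                      c(0.7, 0.5), 0.6, c(40L, 30L, 20L))
  v2p <- voxel_to_patient(g)
  expect_false(v2p$rigid)

  origin <- apply_transform(v2p, landmark_set("o", matrix(0, 1, 3), "VOXEL"))
  expect_equal(unname(origin$coords[1, ]), c(-100, -120, -50))

  g0 <- dicom_geometry(c(0, 0, 0), c(1, 0, 0, 0, 1, 0), c(0.7, 0.5), 0.6,
                       c(40L, 30L, 20L))
  step <- apply_transform(voxel_to_patient(g0),
                          landmark_set("c", matrix(c(1, 0, 0), 1), "VOXEL"))
  expect_equal(unname(step$coords[1, ]), c(0.5, 0, 0))  # column spacing

  set.seed(9)
  idx <- landmark_set(paste0("v", 1:10),
                      cbind(sample(0:29, 10, TRUE), sample(0:39, 10, TRUE),
                            sample(0:19, 10, TRUE)), "VOXEL")
  round_trip <- apply_transform(invert_transform(v2p),
                                apply_transform(v2p, idx))
  expect_lt(max(abs(round_trip$coords - idx$coords)), 1e-9)

  # grid corners span a parallelepiped with the expected edge lengths
  corners <- landmark_set(
    c("o", "c", "r", "s"),
    rbind(c(0, 0, 0), c(29, 0, 0), c(0, 39, 0), c(0, 0, 19)), "VOXEL")
  cc <- apply_transform(v2p, corners)$coords
  expect_equal(sqrt(sum((cc["c", ] - cc["o", ])^2)), 29 * 0.5)
  expect_equal(sqrt(sum((cc["r", ] - cc["o", ])^2)), 39 * 0.7)
  expect_equal(sqrt(sum((cc["s", ] - cc["o", ])^2)), 19 * 0.6)
})

test_that("ips_to_bl reduces to the RAS/LPS flip at zero offset and is rigid", {
  g0 <- dicom_geometry(c(0, 0, 0), c(1, 0, 0, 0, 1, 0), c(0.5, 0.5), 0.6,
                       c(64L, 64L, 32L))
  expect_equal(ips_to_bl(g0)$matrix, ras_lps_flip()$matrix)

  g <- dicom_geometry(c(-128, -100, -40), c(1, 0, 0, 0, 1, 0), c(0.5, 0.5),
                      0.6, c(64L, 64L, 32L))
  tr <- ips_to_bl(g)
  expect_true(tr$rigid)
  set.seed(10)
  pts <- random_landmarks(8, frame = "IPS_IMAGE")
  expect_equal(as.numeric(dist(apply_transform(tr, pts)$coords)),
               as.numeric(dist(pts$coords)), tolerance = 1e-12)
  rt <- compose(tr, invert_transform(tr))
  expect_lt(max(abs(rt$matrix - diag(4))), 1e-12)
})

test_that("dicom_geometry validates direction cosines and spacings", {
  expect_error(dicom_geometry(c(0, 0, 0), c(2, 0, 0, 0, 1, 0), c(0.5, 0.5),
                              0.6, c(64, 64, 10)),
               class = "geometry_error")
  expect_error(dicom_geometry(c(0, 0, 0), c(1, 0, 0, 1, 0, 0), c(0.5, 0.5),
                              0.6, c(64, 64, 10)),
               class = "geometry_error")
  expect_error(dicom_geometry(c(0, 0, 0), c(1, 0, 0, 0, 1, 0), c(0.5, -0.5),
                              0.6, c(64, 64, 10)),
               class = "geometry_error")
})

test_that("landmark sets enforce labels, finiteness and frame pairing", {
  expect_error(landmark_set(c("a", "a"), rbind(c(0, 0, 0), c(1, 1, 1)),
                            "PATIENT"),
               class = "landmark_error")
  expect_error(landmark_set("a", matrix(c(1, NA, 0), 1), "PATIENT"),
               class = "landmark_error")
  pts <- random_landmarks(4)
  expect_error(apply_transform(random_rigid("DRF", "BL_IMAGE"), pts),
               class = "frame_chain_error")
  expect_error(subset_landmarks(pts, c("p1", "zz")), class = "pairing_error")
})
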