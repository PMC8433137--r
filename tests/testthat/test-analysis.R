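toy_targets <- function() {
  landmark_set(c("orbital_rim_L", "orbital_rim_R", "far", "near"),
               rbind(c(-18, 18, 38), c(18, 18, 38), c(0, -140, 60), c(0, 0, 0)),
               "PATIENT")
}

test_that("covariates: sqrt response, distances, rim-anchored centering", {
  tg <- toy_targets()
  recs <- data.frame(target = tg$labels, tre_mm = c(4, 1, 2.25, 0))
  out <- compute_covariates(recs, splint_centroid = c(0, 0, 0), targets = tg)
  expect_equal(out$sqrt_tre, c(2, 1, 1.5, 0))
  expect_equal(out$target_distance_mm[4], 0)  # target at the centroid
  rim_rows <- out$target %in% c("orbital_rim_L", "orbital_rim_R")
  expect_lt(abs(mean(out$centered_distance_mm[rim_rows])), 1e-9)
  expect_equal(out$sqrt_tre^2, out$tre_mm, tolerance = 1e-12)

  # a single rim landmark is its own anchor
  one <- compute_covariates(recs, c(0, 0, 0), tg,
                            infraorbital_labels = "orbital_rim_L")
  expect_equal(one$centered_distance_mm[1], 0)

  expect_error(compute_covariates(recs, c(0, 0, 0), tg,
                                  infraorbital_labels = "infra_missing"),
               class = "covariate_error")
})

test_that("centering is invariant to a constant added to all distances", {
  tg <- toy_targets()
  recs <- data.frame(target = tg$labels, tre_mm = 1:4)
  a <- compute_covariates(recs, c(0, 0, 0), tg)
  shifted <- landmark_set(tg$labels,
                          tg$coords + matrix(rep(c(500, 0, 0), each = 4), 4),
                          "PATIENT")
  b <- compute_covariates(recs, c(500, 0, 0), shifted)
  expect_equal(a$centered_distance_mm, b$centered_distance_mm,
               tolerance = 1e-9)
})

test_that("the mixed model recovers known coefficients and drops aliased cells", {
  truth <- published_study_estimates()
  gl <- derive_group_lines(truth)
  recs <- simulate_from_group_lines(gl, study_design(), make_phantom(2),
                                    cadaver_sd = 0.05, residual_sd = 0.15,
                                    seed = 12)
  fit <- fit_lmm(recs)
  expect_true(fit$converged)
  expect_setequal(fit$fixed_effects$term, truth$term)
  # structurally absent optical surface-based cells are dropped, not guessed
  expect_true(any(grepl("surface_based", fit$dropped_terms)))
  m <- merge(fit$fixed_effects, truth, by = "term",
             suffixes = c("_fit", "_true"))
  expect_true(all(abs(m$estimate_fit - m$estimate_true) <= 3 * m$sd_fit))
})

test_that("a constant response yields a degenerate intercept-only fit", {
  recs <- simulate_from_group_lines(
    data.frame(technique = c("optical", "optical", "EM", "EM", "EM"),
               method = c("bone_anchored", "registration_free",
                          "bone_anchored", "surface_based",
                          "registration_free"),
               intercept = 1.3, slope = 0),
    study_design(n_observers = 1L, n_repetitions = 1L, n_cadavers = 2L,
                 missing_records = integer(0)),
    make_phantom(3), cadaver_sd = 0, residual_sd = 0, seed = 4)
  fit <- fit_lmm(recs)
  fe <- fit$fixed_effects
  expect_equal(fe$estimate[fe$term == "intercept"], 1.3, tolerance = 1e-8)
  expect_true(all(abs(fe$estimate[fe$term != "intercept"]) < 1e-8))
})

test_that("fit is invariant to record order", {
  gl <- derive_group_lines(published_study_estimates())
  recs <- simulate_from_group_lines(gl, study_design(n_repetitions = 2L),
                                    make_phantom(4), seed = 9)
  f1 <- fit_lmm(recs)
  set.seed(10)
  f2 <- fit_lmm(recs[sample(nrow(recs)), ])
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-10)
})

test_that("group lines are an exactly linear readout of the fixed effects", {
  set.seed(11)
  terms <- published_study_estimates()$term
  t1 <- data.frame(term = terms, estimate = rnorm(10))
  t2 <- data.frame(term = terms, estimate = rnorm(10))
  sum_t <- data.frame(term = terms, estimate = t1$estimate + t2$estimate)
  l1 <- derive_group_lines(t1); l2 <- derive_group_lines(t2)
  ls <- derive_group_lines(sum_t)
  expect_equal(ls$intercept, l1$intercept + l2$intercept, tolerance = 1e-12)
  expect_equal(ls$slope, l1$slope + l2$slope, tolerance = 1e-12)

  # intercept-only table: every group gets (k, distance term)
  t0 <- data.frame(term = terms, estimate = c(2.5, 0.01, rep(0, 8)))
  l0 <- derive_group_lines(t0)
  expect_true(all(l0$intercept == 2.5))
  expect_true(all(l0$slope == 0.01))

  missing <- t1[t1$term != "technique_em", ]
  err <- tryCatch(derive_group_lines(missing), error = identity)
  expect_s3_class(err, "derivation_error")
  expect_match(conditionMessage(err), "technique_em")
})

test_that("threshold proportions use strict inequality per observed group", {
  recs <- data.frame(technique = "EM", method = "bone_anchored",
                     tre_mm = c(1, 3))
  expect_equal(proportion_above(recs, 2)$proportion, 0.5)
  expect_equal(proportion_above(data.frame(technique = "EM",
                                           method = "bone_anchored",
                                           tre_mm = c(0.5, 2)), 2)$proportion,
               0)  # exactly-at-threshold does not count

  set.seed(13)
  big <- data.frame(
    technique = sample(c("optical", "EM"), 100, TRUE),
    method = sample(c("bone_anchored", "registration_free"), 100, TRUE),
    tre_mm = rexp(100))
  pa <- proportion_above(big, 1.5)
  for (i in seq_len(nrow(pa))) {
    rows <- big$technique == pa$technique[i] & big$method == pa$method[i]
    expect_identical(pa$n_above[i], sum(big$tre_mm[rows] > 1.5))
    expect_identical(pa$n[i], sum(rows))
  }
  # unobserved groups are absent, not reported as zero
  expect_false(any(pa$method == "surface_based"))
})

test_that("distribution summaries normalize and sqrt reduces skewness", {
  set.seed(14)
  recs <- data.frame(technique = "EM", method = "registration_free",
                     tre_mm = rlnorm(400, meanlog = 0, sdlog = 0.6))
  ds <- distribution_summary(recs)[[1]]
  expect_identical(ds$n, 400L)
  expect_equal(sum(ds$counts), 400L)
  grid_mass <- sum(diff(ds$density$x) *
                     (head(ds$density$y, -1) + tail(ds$density$y, -1)) / 2)
  expect_lt(abs(grid_mass - 1), 1e-3)
  expect_lt(abs(ds$skewness_sqrt), abs(ds$skewness))

  single <- distribution_summary(
    data.frame(technique = "EM", method = "bone_anchored", tre_mm = 1.2))
  expect_null(single[[1]]$density)
  expect_identical(single[[1]]$n, 1L)
})

test_that("per-specimen study covariates anchor each cadaver at its rim", {
  des <- study_design(
    methods_by_technique = list(optical = "bone_anchored",
                                EM = "bone_anchored"),
    n_observers = 1L, n_repetitions = 1L, n_cadavers = 2L,
    missing_records = integer(0))
  study <- simulate_study(des, phantom_seeds = 31L, noise_model())
  out <- study_covariates(study)
  expect_false(anyNA(out$centered_distance_mm))
  for (cad in 1:2) {
    rim <- out$cadaver == cad & out$target %in% c("orbital_rim_L",
                                                  "orbital_rim_R")
    expect_lt(abs(mean(out$centered_distance_mm[rim])), 1e-9)
  }
})
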