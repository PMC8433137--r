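#' Noise model for simulated acquisition sessions
#'
#' Parameterizes the plausible error sources of the navigation workflow.
#' The study being emulated reports only end-to-end error, so these
#' magnitudes are configuration, not estimates derived from it: the defaults
#' were chosen once to land end-to-end TRE in the ~1-2 mm range typical of
#' craniofacial navigation.
#'
#' All localization SDs are isotropic per-axis standard deviations in mm.
#'
#' @param fle_sigma_mm Fiducial/surface-point localization SD per technique;
#'   scalar or named vector with entries `optical`, `EM`.
#' @param seating_rot_sd_deg SD of the splint seating rotation error, degrees
#'   per axis.
#' @param seating_trans_sd_mm SD of the splint seating translation error, mm
#'   per axis.
#' @param pointer_sigma_mm SD of the pointer-tip localization at a target, mm
#'   per axis.
#' @param icp_init_rot_sd_deg,icp_init_trans_sd_mm Spread of the coarse
#'   initial pose handed to surface-based registration.
#' @param n_surface_points Number of skin points acquired for surface-based
#'   registration.
#' @param icp_max_iterations,icp_tol ICP settings used by simulated
#'   surface-based sessions (looser than the [register_surface()] defaults:
#'   with localization noise the RMS plateau is reached long before 1e-6 mm).
#' @return Object of class `noise_model`.
#' @export
#' @examples
#' noise_model()                # study defaults
#' noise_model(0, 0, 0, 0, 0, 0)  # noise-free
noise_model <- function(fle_sigma_mm = c(optical = 0.25, EM = 0.3),
                        seating_rot_sd_deg = 0.2,
                        seating_trans_sd_mm = 0.3,
                        pointer_sigma_mm = 0.15,
                        icp_init_rot_sd_deg = 2,
                        icp_init_trans_sd_mm = 2,
                        n_surface_points = 40L,
                        icp_max_iterations = 100L,
                        icp_tol = 1e-5) {
  if (length(fle_sigma_mm) == 1L && is.null(names(fle_sigma_mm))) {
    fle_sigma_mm <- c(optical = unname(fle_sigma_mm), EM = unname(fle_sigma_mm))
  }
  stopifnot(all(c("optical", "EM") %in% names(fle_sigma_mm)))
  vals <- c(fle_sigma_mm, seating_rot_sd_deg, seating_trans_sd_mm,
            pointer_sigma_mm, icp_init_rot_sd_deg, icp_init_trans_sd_mm)
  if (any(vals < 0) || anyNA(vals)) {
    nav_abort("noise standard deviations must be non-negative",
              "input_error")
  }
  structure(list(fle_sigma_mm = fle_sigma_mm,
                 seating_rot_sd_deg = seating_rot_sd_deg,
                 seating_trans_sd_mm = seating_trans_sd_mm,
                 pointer_sigma_mm = pointer_sigma_mm,
                 icp_init_rot_sd_deg = icp_init_rot_sd_deg,
                 icp_init_trans_sd_mm = icp_init_trans_sd_mm,
                 n_surface_points = as.integer(n_surface_points),
                 icp_max_iterations = as.integer(icp_max_iterations),
                 icp_tol = icp_tol),
            class = "noise_model")
}

#' Factorial design of the accuracy study
#'
#' The study crosses tracking technique and registration method (surface-based
#' registration exists only for electromagnetic tracking), observers,
#' repetitions and specimens; every session acquires all targets. With the
#' defaults the full enumeration has 5 arms x 2 observers x 5 repetitions x
#' 5 cadavers x 14 targets = 3500 records, of which 4 registration-free
#' records are dropped as missing, leaving 3496.
#'
#' @param methods_by_technique Named list mapping each technique to its valid
#'   registration methods.
#' @param n_observers,n_repetitions,n_cadavers Positive counts.
#' @param missing_records Integer vector of row indices (into the fully
#'   enumerated record order: cadaver, technique, method, observer,
#'   repetition, target, slowest to fastest) to drop, or `NULL` for the
#'   default of 4 deterministic registration-free records. Use `integer(0)`
#'   to drop none.
#' @return Object of class `study_design`.
#' @export
study_design <- function(methods_by_technique = list(
                           optical = c("bone_anchored", "registration_free"),
                           EM = c("bone_anchored", "surface_based",
                                  "registration_free")),
                         n_observers = 2L,
                         n_repetitions = 5L,
                         n_cadavers = 5L,
                         missing_records = NULL) {
  stopifnot(is.list(methods_by_technique),
            length(methods_by_technique) >= 1L,
            !is.null(names(methods_by_technique)),
            n_observers >= 1L, n_repetitions >= 1L, n_cadavers >= 1L)
  if (!is.null(missing_records)) {
    missing_records <- as.integer(missing_records)
    if (anyDuplicated(missing_records)) {
      nav_abort("missing_records indices must be unique", "input_error")
    }
  }
  structure(list(methods_by_technique = methods_by_technique,
                 n_observers = as.integer(n_observers),
                 n_repetitions = as.integer(n_repetitions),
                 n_cadavers = as.integer(n_cadavers),
                 missing_records = missing_records),
            class = "study_design")
}

.check_method <- function(technique, method, design = study_design()) {
  valid <- design$methods_by_technique[[technique]]
  if (is.null(valid)) {
    nav_abort(sprintf("unknown tracking technique '%s'", technique),
              "design_error")
  }
  if (!method %in% valid) {
    nav_abort(sprintf("registration method '%s' is not available with %s tracking",
                      method, technique), "design_error")
  }
  invisible(TRUE)
}

.rand_rigid <- function(from, to, max_angle_deg = 180, max_trans_mm = 100) {
  euler_transform(stats::runif(3L, -max_angle_deg, max_angle_deg),
                  stats::runif(3L, -max_trans_mm, max_trans_mm), from, to)
}

#' Simulate one acquisition session
#'
#' One session = one registration (or splint seating) followed by a pointer
#' acquisition at every phantom target, as performed intra-operatively:
#'
#' * `bone_anchored`: the five fiducial screws are localized in physical
#'   space with localization noise, point-based registration is fit against
#'   the (exact) image-space fiducials, and noisy target acquisitions are
#'   mapped through the fitted registration.
#' * `surface_based` (EM only): skin points are sampled on the phantom's skin
#'   surface, perturbed by localization noise, and registered to the
#'   image-space skin mesh by ICP from a coarse initial pose.
#' * `registration_free`: a splint seating perturbation displaces the DRF
#'   from its designed pose; acquisitions are recorded relative to the seated
#'   DRF through an arbitrary pre-registration, then recalculated through the
#'   design-side transform chain ([build_chain()], [correct_preregistration()],
#'   [to_image_space()]). The recalculated coordinates do not depend on the
#'   pre-registration used.
#'
#' @param phantom A [make_phantom()] result.
#' @param technique `"optical"` or `"EM"`.
#' @param method `"bone_anchored"`, `"surface_based"` or `"registration_free"`.
#' @param noise A [noise_model()].
#' @param seed Integer seed; a fixed seed reproduces the session exactly.
#' @param cadaver,observer,repetition Metadata recorded on each row.
#' @param prereg Optional rigid `nav_transform` (`DRF -> BL_IMAGE`) to use as
#'   the recorded pre-registration of a registration-free session; by default
#'   an arbitrary seeded rigid transform is drawn. Ignored by other methods.
#' @return A data.frame with one row per target: `cadaver`, `technique`,
#'   `method`, `observer`, `repetition`, `target`, `x`, `y`, `z` (the final
#'   image-space coordinate: `c` for conventional registration, the
#'   recalculated `c''` for registration-free), `frame`, `tre_mm`.
#'   Attribute `t_reg` holds the session's registration (or pre-registration)
#'   transform; `fre_mm` the fiducial/surface residual where applicable.
#' @export
simulate_session <- function(phantom, technique, method, noise, seed,
                             cadaver = 1L, observer = 1L, repetition = 1L,
                             prereg = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(noise, "noise_model"))
  technique <- match.arg(technique, c("optical", "EM"))
  method <- match.arg(method, c("bone_anchored", "surface_based",
                                "registration_free"))
  .check_method(technique, method)
  sigma <- unname(noise$fle_sigma_mm[[technique]])
  targets <- phantom$targets
  n_t <- length(targets$labels)

  .with_seed(seed, {
    pointer_noise <- matrix(stats::rnorm(n_t * 3L, 0, noise$pointer_sigma_mm),
                            n_t, 3L)
    t_phys <- targets$coords + pointer_noise

    if (method == "bone_anchored") {
      n_f <- length(phantom$fiducials$labels)
      f_phys <- phantom$fiducials$coords +
        matrix(stats::rnorm(n_f * 3L, 0, sigma), n_f, 3L)
      reg <- register_point_based(
        landmark_set(phantom$fiducials$labels, f_phys, "PATIENT"),
        phantom$fiducials_image)
      c_img <- apply_transform_xyz(reg$transform, t_phys)
      t_reg <- reg$transform
      fre_mm <- reg$fre_mm
    } else if (method == "surface_based") {
      probe <- sample_mesh_points(phantom$skin_surface_patient,
                                  noise$n_surface_points)
      probe <- landmark_set(
        probe$labels,
        probe$coords + matrix(stats::rnorm(length(probe$labels) * 3L, 0, sigma),
                              ncol = 3L),
        "PATIENT")
      init <- compose(
        euler_transform(stats::rnorm(3L, 0, noise$icp_init_rot_sd_deg),
                        stats::rnorm(3L, 0, noise$icp_init_trans_sd_mm),
                        "PATIENT", "PATIENT"),
        phantom$true_ct_pose)
      reg <- register_surface(probe, phantom$skin_surface, init,
                              max_iterations = noise$icp_max_iterations,
                              tol = noise$icp_tol)
      c_img <- apply_transform_xyz(reg$transform, t_phys)
      t_reg <- reg$transform
      fre_mm <- reg$fre_mm
    } else { # registration_free
      seating <- euler_transform(
        stats::rnorm(3L, 0, noise$seating_rot_sd_deg),
        stats::rnorm(3L, 0, noise$seating_trans_sd_mm), "DRF", "DRF")
      drf_seated <- compose(seating, phantom$drf_pose_patient)
      p_drf <- apply_transform_xyz(invert_transform(drf_seated), t_phys)
      if (is.null(prereg)) {
        prereg <- .rand_rigid("DRF", "BL_IMAGE")
      }
      stopifnot(inherits(prereg, "nav_transform"))
      c_acq <- landmark_set(targets$labels,
                            apply_transform_xyz(prereg, p_drf), prereg$to)
      chain <- build_chain(phantom$splint_design, phantom$geometry)
      c_img <- to_image_space(
        correct_preregistration(c_acq, prereg), chain)$coords
      t_reg <- prereg
      fre_mm <- NA_real_
    }
  })

  err <- sqrt(rowSums((c_img - phantom$targets_image$coords)^2))
  out <- data.frame(
    cadaver = as.integer(cadaver), technique = technique, method = method,
    observer = as.integer(observer), repetition = as.integer(repetition),
    target = targets$labels,
    x = c_img[, 1], y = c_img[, 2], z = c_img[, 3],
    frame = "BL_IMAGE", tre_mm = unname(err),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "t_reg") <- t_reg
  attr(out, "fre_mm") <- fre_mm
  out
}

#' Simulate the full factorial accuracy study
#'
#' Enumerates every (cadaver, technique, method, observer, repetition)
#' session of the design, simulating each with a seed derived by stable
#' hashing of its metadata tuple (so the dataset is independent of
#' enumeration order), and drops the design's missing records. Each cadaver
#' gets its own phantom.
#'
#' @param design A [study_design()].
#' @param phantom_seeds Integer vector of length `n_cadavers` (or a single
#'   master seed from which per-cadaver seeds are derived).
#' @param noise A [noise_model()].
#' @return A data.frame of acquisition records as in [simulate_session()],
#'   plus a `row_id` column giving each record's index in the full
#'   enumeration (the index space of `missing_records`). Attribute
#'   `phantoms` holds the per-cadaver phantom list.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(study_design(), phantom_seeds = 1:5, noise_model())
#' nrow(study)  # 3496 with the default design
#' }
simulate_study <- function(design = study_design(), phantom_seeds,
                           noise = noise_model()) {
  stopifnot(inherits(design, "study_design"))
  if (length(phantom_seeds) == 1L) {
    phantom_seeds <- vapply(seq_len(design$n_cadavers), function(i)
      .derive_seed(phantom_seeds, "cadaver", i), integer(1))
  }
  stopifnot(length(phantom_seeds) == design$n_cadavers)
  phantoms <- lapply(phantom_seeds, make_phantom)

  sessions <- list()
  for (cad in seq_len(design$n_cadavers)) {
    for (technique in names(design$methods_by_technique)) {
      for (method in design$methods_by_technique[[technique]]) {
        for (obs in seq_len(design$n_observers)) {
          for (rep_i in seq_len(design$n_repetitions)) {
            s <- simulate_session(
              phantoms[[cad]], technique, method, noise,
              seed = .derive_seed(phantom_seeds[cad], technique, method,
                                  obs, rep_i),
              cadaver = cad, observer = obs, repetition = rep_i)
            sessions[[length(sessions) + 1L]] <- s
          }
        }
      }
    }
  }
  all <- do.call(rbind, sessions)
  all$row_id <- seq_len(nrow(all))
  missing <- design$missing_records %||% .default_missing_records(all)
  if (length(missing)) {
    if (any(missing < 1L | missing > nrow(all))) {
      nav_abort("missing_records indices out of range", "input_error")
    }
    all <- all[-missing, , drop = FALSE]
  }
  rownames(all) <- NULL
  attr(all, "phantoms") <- phantoms
  all
}

# Default missingness: 4 registration-free records at deterministic spread
# positions, emulating occasional failed acquisitions in that arm.
.default_missing_records <- function(records) {
  idx <- records$row_id[records$method == "registration_free"]
  if (length(idx) < 4L) return(integer(0))
  idx[round(c(0.2, 0.4, 0.6, 0.8) * length(idx))]
}

#' Simulate square-root TRE records directly from group lines
#'
#' Model-based counterpart of [simulate_study()]: instead of simulating the
#' acquisition physics, draws `sqrt(TRE)` from the accuracy model itself --
#' per-group intercept and slope on the centered target distance, a random
#' cadaver intercept, and residual noise. Used to check that the fitting
#' pipeline recovers known group lines.
#'
#' @param group_lines data.frame with columns `technique`, `method`,
#'   `intercept` (sqrt-mm at the infraorbital rim) and `slope`
#'   (sqrt-mm per mm).
#' @param design A [study_design()].
#' @param phantom A [make_phantom()] result supplying the target-distance
#'   covariate.
#' @param cadaver_sd SD of the random cadaver intercept.
#' @param residual_sd Residual SD on the sqrt scale.
#' @param seed Integer seed.
#' @return A data.frame of TRE records with covariates (`tre_mm`, `sqrt_tre`,
#'   `target_distance_mm`, `centered_distance_mm`) ready for [fit_lmm()].
#' @export
simulate_from_group_lines <- function(group_lines, design = study_design(),
                                      phantom = make_phantom(1L),
                                      cadaver_sd = 0.05, residual_sd = 0.15,
                                      seed = 1L) {
  stopifnot(is.data.frame(group_lines),
            all(c("technique", "method", "intercept", "slope") %in%
                  names(group_lines)))
  d <- target_distances(phantom)
  rim <- grep("^orbital_rim", names(d), value = TRUE)
  if (!length(rim)) {
    nav_abort("phantom targets lack infraorbital rim landmarks",
              "covariate_error")
  }
  dc <- d - mean(d[rim])

  rows <- list()
  for (cad in seq_len(design$n_cadavers)) {
    for (technique in names(design$methods_by_technique)) {
      for (method in design$methods_by_technique[[technique]]) {
        for (obs in seq_len(design$n_observers)) {
          for (rep_i in seq_len(design$n_repetitions)) {
            rows[[length(rows) + 1L]] <- data.frame(
              cadaver = cad, technique = technique, method = method,
              observer = obs, repetition = rep_i, target = names(d),
              target_distance_mm = unname(d),
              centered_distance_mm = unname(dc),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  recs <- do.call(rbind, rows)
  recs$row_id <- seq_len(nrow(recs))
  missing <- design$missing_records %||% .default_missing_records(recs)
  if (length(missing)) recs <- recs[-missing, , drop = FALSE]

  key <- paste(recs$technique, recs$method)
  gkey <- paste(group_lines$technique, group_lines$method)
  gi <- match(key, gkey)
  if (anyNA(gi)) {
    nav_abort(sprintf("no group line for cell(s): %s",
                      paste(unique(key[is.na(gi)]), collapse = ", ")),
              "input_error")
  }
  .with_seed(seed, {
    b_cad <- stats::rnorm(design$n_cadavers, 0, cadaver_sd)
    mu <- group_lines$intercept[gi] +
      group_lines$slope[gi] * recs$centered_distance_mm
    recs$sqrt_tre <- pmax(0, mu + b_cad[recs$cadaver] +
                            stats::rnorm(nrow(recs), 0, residual_sd))
  })
  recs$tre_mm <- recs$sqrt_tre^2
  rownames(recs) <- NULL
  recs
}
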