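#' Controlled target-landmark vocabulary
#'
#' The fourteen cranial target positions of the accuracy study: bilateral
#' orbital rim, zygomatic prominence, lateral orbital wall, porion, frontal
#' bone and occipital bone, plus nasion and cranial vertex.
#'
#' @return Character vector of 14 target labels.
#' @export
target_vocabulary <- function() {
  c("orbital_rim_L", "orbital_rim_R", "zygoma_L", "zygoma_R",
    "lateral_orbital_wall_L", "lateral_orbital_wall_R",
    "porion_L", "porion_R", "nasion", "frontal_L", "frontal_R",
    "cranium", "occipital_L", "occipital_R")
}

# Nominal head geometry, mm, PATIENT frame: x right, y anterior, z superior,
# origin at the center of the maxillary dental arch. Values approximate adult
# cranial anatomy; bilateral symmetry by construction.
.TARGET_BASE <- rbind(
  orbital_rim_L          = c(-18,   18,  38),
  orbital_rim_R          = c( 18,   18,  38),
  zygoma_L               = c(-45,    5,  40),
  zygoma_R               = c( 45,    5,  40),
  lateral_orbital_wall_L = c(-38,    8,  52),
  lateral_orbital_wall_R = c( 38,    8,  52),
  porion_L               = c(-55,  -40,  35),
  porion_R               = c( 55,  -40,  35),
  nasion                 = c(  0,   25,  60),
  frontal_L              = c(-25,   15,  95),
  frontal_R              = c( 25,   15,  95),
  cranium                = c(  0,  -30, 165),
  occipital_L            = c(-35, -140,  45),
  occipital_R            = c( 35, -140,  45)
)

# Five maxillary fiducial screws above the dental roots: a ~40 x 22 mm patch
# with little craniocaudal (z) spread, i.e. nearly coplanar, as when screws
# are placed along the alveolar process.
.FIDUCIAL_BASE <- rbind(
  fid1 = c(-20, 24, 10),
  fid2 = c(-10, 40, 12),
  fid3 = c(  0, 46,  9),
  fid4 = c( 10, 40, 11),
  fid5 = c( 20, 24, 10)
)

# Maxillary dental arch sampled as a parabola; stands in for the splint
# surface seated on the dentition (centroid is what downstream code uses).
.splint_arch_points <- function() {
  t <- seq(-1, 1, length.out = 21)
  cbind(28 * t, 42 * (1 - t^2), rep(c(0, 3), length.out = 21))
}

#' Generate a synthetic cadaver-head phantom
#'
#' Builds one synthetic specimen of the accuracy study: five near-coplanar
#' maxillary fiducial screws, fourteen cranial target screws at the named
#' landmarks (target distances from the splint centroid spanning roughly
#' 40-180 mm, bilaterally symmetric up to jitter), a splint-borne DRF design
#' whose pose in planning image space is derived from the ground-truth CT
#' pose, a coarse ellipsoidal skin surface for surface-based registration,
#' and the CT header geometry. Deterministic for a given seed; per-specimen
#' anatomical variation is emulated with small seeded jitter.
#'
#' @param seed Integer seed controlling the specimen's jitter and CT pose.
#' @param overrides Optional named list replacing generated components:
#'   `targets` and/or `fiducials` ([landmark_set]s in `PATIENT`; fiducials
#'   need >= 3 points), `geometry` (a [dicom_geometry]), `true_ct_pose`
#'   (rigid `PATIENT -> BL_IMAGE`), `skin_semiaxes`, `skin_center`.
#' @return Object of class `phantom_spec` with fields `fiducials`, `targets`
#'   (both `PATIENT`), `fiducials_image`, `targets_image` (both `BL_IMAGE`),
#'   `splint_design`, `skin_surface` (`BL_IMAGE`), `skin_surface_patient`,
#'   `drf_pose_patient` (`DRF -> PATIENT`), `true_ct_pose`
#'   (`PATIENT -> BL_IMAGE`), `geometry`, `seed`.
#' @export
#' @examples
#' ph <- make_phantom(17)
#' range(target_distances(ph))
make_phantom <- function(seed, overrides = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  unknown <- setdiff(names(overrides),
                     c("targets", "fiducials", "geometry", "true_ct_pose",
                       "skin_semiaxes", "skin_center"))
  if (length(unknown)) {
    nav_abort(sprintf("unknown phantom overrides: %s",
                      paste(unknown, collapse = ", ")), "input_error")
  }
  .with_seed(.derive_seed(seed, "phantom"), {
    tjit <- matrix(stats::rnorm(14L * 3L, 0, 2), 14L, 3L)
    fjit <- cbind(matrix(stats::rnorm(5L * 2L, 0, 1.5), 5L, 2L),
                  stats::rnorm(5L, 0, 0.4))
    pose_angles <- stats::runif(3L, -8, 8)
    pose_offset <- c(-2, -15, 40) + stats::rnorm(3L, 0, 5)
  })

  targets <- overrides$targets %||%
    landmark_set(rownames(.TARGET_BASE), .TARGET_BASE + tjit, "PATIENT")
  fiducials <- overrides$fiducials %||%
    landmark_set(rownames(.FIDUCIAL_BASE), .FIDUCIAL_BASE + fjit, "PATIENT")
  if (is.null(overrides$targets) &&
      !setequal(targets$labels, target_vocabulary())) {
    nav_abort("default phantom targets must match the target vocabulary",
              "input_error")
  }
  if (length(fiducials$labels) < 3L) {
    nav_abort("phantom needs at least 3 fiducials", "input_error")
  }
  .check_frames_link(targets$frame, "PATIENT", "make_phantom")
  .check_frames_link(fiducials$frame, "PATIENT", "make_phantom")

  geometry <- overrides$geometry %||%
    dicom_geometry(c(-128, -128, -90), c(1, 0, 0, 0, 1, 0),
                   c(0.5, 0.5), 0.6, c(512L, 512L, 300L))
  true_ct_pose <- overrides$true_ct_pose %||%
    euler_transform(pose_angles, pose_offset, "PATIENT", "BL_IMAGE")
  if (!true_ct_pose$rigid) {
    nav_abort("true_ct_pose must be rigid", "rigidity_error")
  }

  # DRF seated on the splint, anterior to the incisors, slightly tilted
  drf_pose_patient <- euler_transform(c(15, 0, 0), c(0, 45, 10),
                                      "DRF", "PATIENT")

  t_bl_ips <- invert_transform(ips_to_bl(geometry))
  patient_to_ips <- compose(true_ct_pose, t_bl_ips)
  arch_patient <- .splint_arch_points()
  arch_ips <- apply_transform_xyz(patient_to_ips, arch_patient)
  design <- splint_design(
    drf_pose_ips = compose(drf_pose_patient, patient_to_ips),
    splint_vertices = arch_ips
  )

  skin_patient <- synthetic_face_mesh(
    semiaxes = overrides$skin_semiaxes %||% c(75, 95, 105),
    center = overrides$skin_center %||% c(0, -70, 60),
    frame = "PATIENT"
  )
  skin_image <- surface_model(
    apply_transform_xyz(true_ct_pose, skin_patient$vertices),
    skin_patient$faces, "BL_IMAGE"
  )

  structure(
    list(fiducials = fiducials,
         targets = targets,
         fiducials_image = apply_transform(true_ct_pose, fiducials),
         targets_image = apply_transform(true_ct_pose, targets),
         splint_design = design,
         skin_surface = skin_image,
         skin_surface_patient = skin_patient,
         drf_pose_patient = drf_pose_patient,
         true_ct_pose = true_ct_pose,
         geometry = geometry,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> seed %d: %d fiducials, %d targets, skin %d faces\n",
    x$seed, length(x$fiducials$labels), length(x$targets$labels),
    nrow(x$skin_surface$faces)))
  invisible(x)
}

#' Target distances from the splint centroid
#'
#' Euclidean distance of each phantom target to the splint centroid, the
#' distance covariate of the accuracy analysis. Computed in patient space
#' (distances are invariant to the rigid image pose).
#'
#' @param phantom A `phantom_spec`.
#' @return Named numeric vector, mm.
#' @export
target_distances <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  centroid_ips <- splint_centroid(phantom$splint_design)
  ips_to_patient <- invert_transform(
    compose(phantom$true_ct_pose, invert_transform(ips_to_bl(phantom$geometry))))
  centroid <- as.numeric(apply_transform_xyz(ips_to_patient, centroid_ips))
  d <- sqrt(rowSums(sweep(phantom$targets$coords, 2L, centroid)^2))
  names(d) <- phantom$targets$labels
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state so library calls do not disturb the
# caller's stream; seeds derived from metadata stay below 2^31.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

.derive_seed <- function(...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "|")
  h <- 17
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483629
  as.integer(h)
}
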