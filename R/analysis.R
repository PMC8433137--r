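#' Attach accuracy-analysis covariates to TRE records
#'
#' Adds to each record the response and covariates of the accuracy model:
#' `sqrt_tre` (square root of the TRE in mm, the variance-stabilized
#' response), `target_distance_mm` (distance of the record's target from the
#' splint centroid) and `centered_distance_mm` (that distance minus the mean
#' distance of the infraorbital-rim targets, so the model intercept is the
#' expected `sqrt(TRE)` at the infraorbital rim rather than at the splint).
#'
#' @param records data.frame with at least `target` and `tre_mm` columns
#'   (e.g. from [simulate_study()]).
#' @param splint_centroid Numeric length-3 splint centroid, in the same frame
#'   as `targets`.
#' @param targets [landmark_set] of true target positions covering every
#'   target label in `records`.
#' @param infraorbital_labels Labels whose mean distance anchors the
#'   centering (default: the bilateral orbital-rim targets).
#' @return `records` with the three covariate columns appended.
#' @export
compute_covariates <- function(records, splint_centroid, targets,
                               infraorbital_labels = c("orbital_rim_L",
                                                       "orbital_rim_R")) {
  stopifnot(is.data.frame(records),
            all(c("target", "tre_mm") %in% names(records)),
            inherits(targets, "landmark_set"),
            is.numeric(splint_centroid), length(splint_centroid) == 3L)
  if (!all(infraorbital_labels %in% targets$labels)) {
    nav_abort(sprintf("infraorbital labels missing from targets: %s",
                      paste(setdiff(infraorbital_labels, targets$labels),
                            collapse = ", ")),
              "covariate_error")
  }
  unknown <- setdiff(unique(records$target), targets$labels)
  if (length(unknown)) {
    nav_abort(sprintf("record targets missing from target set: %s",
                      paste(unknown, collapse = ", ")), "covariate_error")
  }
  d <- sqrt(rowSums(sweep(targets$coords, 2L, splint_centroid)^2))
  names(d) <- targets$labels
  records$sqrt_tre <- sqrt(records$tre_mm)
  records$target_distance_mm <- unname(d[records$target])
  records$centered_distance_mm <-
    records$target_distance_mm - mean(d[infraorbital_labels])
  records
}

#' Covariates for a multi-specimen simulated study
#'
#' [compute_covariates()] for a whole [simulate_study()] dataset: each
#' cadaver's records get distances from its own phantom's targets and splint
#' centroid, centered at that specimen's infraorbital-rim mean (the anatomy,
#' and hence the covariate, is specimen-specific).
#'
#' @param records Records from [simulate_study()].
#' @param phantoms List of `phantom_spec`, one per cadaver (defaults to the
#'   `phantoms` attribute of `records`).
#' @param infraorbital_labels As in [compute_covariates()].
#' @return `records` with `sqrt_tre`, `target_distance_mm` and
#'   `centered_distance_mm` appended.
#' @export
study_covariates <- function(records, phantoms = attr(records, "phantoms"),
                             infraorbital_labels = c("orbital_rim_L",
                                                     "orbital_rim_R")) {
  stopifnot(is.data.frame(records), is.list(phantoms))
  cads <- sort(unique(records$cadaver))
  if (max(cads) > length(phantoms)) {
    nav_abort("records reference cadavers without a phantom",
              "covariate_error")
  }
  records$sqrt_tre <- sqrt(records$tre_mm)
  records$target_distance_mm <- NA_real_
  records$centered_distance_mm <- NA_real_
  for (cad in cads) {
    d <- target_distances(phantoms[[cad]])
    if (!all(infraorbital_labels %in% names(d))) {
      nav_abort(sprintf("phantom %d lacks infraorbital labels: %s", cad,
                        paste(setdiff(infraorbital_labels, names(d)),
                              collapse = ", ")),
                "covariate_error")
    }
    rows <- records$cadaver == cad
    records$target_distance_mm[rows] <- unname(d[records$target[rows]])
    records$centered_distance_mm[rows] <-
      records$target_distance_mm[rows] - mean(d[infraorbital_labels])
  }
  records
}

.CANONICAL_TERMS <- c(
  "(Intercept)" = "intercept",
  "centered_distance_mm" = "distance",
  "techniqueEM" = "technique_em",
  "methodregistration_free" = "method_registration_free",
  "methodsurface_based" = "method_surface_based",
  "centered_distance_mm:techniqueEM" = "distance_x_technique_em",
  "centered_distance_mm:methodregistration_free" =
    "distance_x_method_registration_free",
  "centered_distance_mm:methodsurface_based" =
    "distance_x_method_surface_based",
  "techniqueEM:methodregistration_free" =
    "technique_em_x_method_registration_free",
  "centered_distance_mm:techniqueEM:methodregistration_free" =
    "distance_x_technique_em_x_method_registration_free"
)

#' Fit the square-root TRE linear mixed model
#'
#' Fits `sqrt_tre ~ centered_distance_mm * technique * method` with random
#' intercepts by REML (default) using lme4. The reference category is
#' bone-anchored registration with optical tracking; structurally absent
#' design cells (surface-based registration exists only under EM tracking)
#' make the full-interaction model matrix rank deficient, and the aliased
#' columns are dropped and reported rather than silently estimated. The
#' random-effects structure defaults to a random intercept per cadaver;
#' crossed random intercepts for observer and/or target can be added.
#'
#' @param records data.frame with `sqrt_tre`, `centered_distance_mm`,
#'   `technique`, `method` and the grouping columns named in
#'   `random_effects`.
#' @param random_effects Character vector of grouping columns receiving
#'   random intercepts (default `"cadaver"`).
#' @param reml Fit by REML (default) or ML.
#' @return Object of class `tre_lmm`: list with `fixed_effects` (data.frame
#'   `term`, `estimate`, `sd`, `t` in canonical term names), `dropped_terms`,
#'   `converged`, `singular`, `reference`, `formula` and the underlying
#'   `fit` (`lmerMod`, or `NULL` for the degenerate zero-variance case).
#' @export
fit_lmm <- function(records, random_effects = "cadaver", reml = TRUE) {
  needed <- c("sqrt_tre", "centered_distance_mm", "technique", "method",
              random_effects)
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    nav_abort(sprintf("records lack required columns: %s",
                      paste(miss, collapse = ", ")), "input_error")
  }
  dat <- records
  dat$technique <- factor(dat$technique,
                          levels = intersect(c("optical", "EM"),
                                             unique(dat$technique)))
  dat$method <- factor(dat$method,
                       levels = intersect(c("bone_anchored",
                                            "registration_free",
                                            "surface_based"),
                                          unique(dat$method)))
  for (g in random_effects) dat[[g]] <- factor(dat[[g]])
  if (nlevels(dat$technique) < 2L || nlevels(dat$method) < 2L) {
    nav_abort("need at least 2 observed levels of technique and method",
              "input_error")
  }

  form <- stats::as.formula(paste(
    "sqrt_tre ~ centered_distance_mm * technique * method +",
    paste(sprintf("(1 | %s)", random_effects), collapse = " + ")))

  if (stats::var(dat$sqrt_tre) < 1e-24) {
    # degenerate: constant response; the fit is the constant itself
    fe <- data.frame(term = unname(.CANONICAL_TERMS),
                     estimate = c(dat$sqrt_tre[1], rep(0, 9L)),
                     sd = 0, t = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(fixed_effects = fe, dropped_terms = character(0),
                          converged = TRUE, singular = TRUE,
                          reference = "optical bone_anchored",
                          formula = form, fit = NULL),
                     class = "tre_lmm"))
  }

  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = reml),
    message = function(m) invokeRestart("muffleMessage")
  )
  co <- as.data.frame(summary(fit)$coefficients)
  raw_terms <- rownames(co)
  canon <- .CANONICAL_TERMS[raw_terms]
  canon[is.na(canon)] <- raw_terms[is.na(canon)]
  fe <- data.frame(term = unname(canon), estimate = co[, "Estimate"],
                   sd = co[, "Std. Error"], t = co[, "t value"],
                   stringsAsFactors = FALSE, row.names = NULL)
  full_cols <- colnames(stats::model.matrix(lme4::nobars(form), dat))
  dropped <- setdiff(full_cols, raw_terms)
  dropped_canon <- ifelse(is.na(.CANONICAL_TERMS[dropped]), dropped,
                          .CANONICAL_TERMS[dropped])
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(fixed_effects = fe,
                 dropped_terms = unname(dropped_canon),
                 converged = is.null(msgs) || length(msgs) == 0L,
                 singular = lme4::isSingular(fit),
                 reference = "optical bone_anchored",
                 formula = form, fit = fit),
            class = "tre_lmm")
}

#' @export
print.tre_lmm <- function(x, ...) {
  cat("<tre_lmm> sqrt(TRE) mixed model",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("  reference:", x$reference, "\n")
  if (length(x$dropped_terms)) {
    cat("  aliased terms dropped:", paste(x$dropped_terms, collapse = ", "),
        "\n")
  }
  print(transform(x$fixed_effects, estimate = round(estimate, 4),
                  sd = round(sd, 4), t = round(t, 2)))
  invisible(x)
}

#' Group intercept and slope lines from fixed effects
#'
#' Recalculates the fitted (or published) fixed-effects table into one
#' intercept/slope line per technique-method combination: the reference
#' category (optical bone-anchored) takes the intercept and distance terms
#' alone, every other group adds its applicable main effects and
#' interactions. Intercepts are in sqrt-mm at the infraorbital rim; slopes in
#' sqrt-mm per mm of target distance. Printing rounds to the conventional 2
#' (intercept) and 4 (slope) decimals; the stored values are exact sums.
#'
#' @param fx data.frame with columns `term` and `estimate` using the
#'   canonical term names (as produced by [fit_lmm()] or
#'   [published_study_estimates()]).
#' @return data.frame of class `group_lines` with columns `technique`,
#'   `method`, `intercept`, `slope` (five rows for the full design).
#' @export
#' @examples
#' derive_group_lines(published_study_estimates())
derive_group_lines <- function(fx) {
  stopifnot(is.data.frame(fx), all(c("term", "estimate") %in% names(fx)))
  est <- stats::setNames(fx$estimate, fx$term)
  need <- unname(.CANONICAL_TERMS)
  miss <- setdiff(need, names(est))
  if (length(miss)) {
    nav_abort(sprintf("fixed-effects table is missing term(s): %s",
                      paste(miss, collapse = ", ")), "derivation_error")
  }
  lines <- rbind(
    data.frame(technique = "optical", method = "bone_anchored",
               intercept = est[["intercept"]],
               slope = est[["distance"]]),
    data.frame(technique = "optical", method = "registration_free",
               intercept = est[["intercept"]] +
                 est[["method_registration_free"]],
               slope = est[["distance"]] +
                 est[["distance_x_method_registration_free"]]),
    data.frame(technique = "EM", method = "bone_anchored",
               intercept = est[["intercept"]] + est[["technique_em"]],
               slope = est[["distance"]] + est[["distance_x_technique_em"]]),
    data.frame(technique = "EM", method = "surface_based",
               intercept = est[["intercept"]] + est[["technique_em"]] +
                 est[["method_surface_based"]],
               slope = est[["distance"]] + est[["distance_x_technique_em"]] +
                 est[["distance_x_method_surface_based"]]),
    data.frame(technique = "EM", method = "registration_free",
               intercept = est[["intercept"]] + est[["technique_em"]] +
                 est[["method_registration_free"]] +
                 est[["technique_em_x_method_registration_free"]],
               slope = est[["distance"]] + est[["distance_x_technique_em"]] +
                 est[["distance_x_method_registration_free"]] +
                 est[["distance_x_technique_em_x_method_registration_free"]])
  )
  rownames(lines) <- NULL
  class(lines) <- c("group_lines", "data.frame")
  lines
}

#' @export
print.group_lines <- function(x, ...) {
  y <- as.data.frame(x)
  y$intercept <- sprintf("%.2f", y$intercept)
  y$slope <- sprintf("%.4f", y$slope)
  print(y)
  invisible(x)
}

#' Published fixed-effect estimates of the cadaver accuracy study
#'
#' The fixed-effect estimate table reported by the cadaver accuracy study of
#' the registration-free workflow (reference category: bone-anchored
#' registration with optical tracking; response sqrt(TRE); distance covariate
#' centered at the infraorbital rim), shipped with the package so derived
#' group lines can be reproduced without the raw measurements.
#'
#' @return data.frame with columns `term` (canonical names), `estimate`,
#'   `sd`, `t`.
#' @export
published_study_estimates <- function() {
  path <- system.file("extdata", "cadaver_study_fixed_effects.csv",
                      package = "regfreenav", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fraction of TRE measurements above a threshold
#'
#' Strict-inequality fraction of records with `tre_mm > threshold_mm`, per
#' technique-method group. Groups with no records are absent from the output
#' rather than reported as zero.
#'
#' @param records data.frame with `technique`, `method`, `tre_mm`.
#' @param threshold_mm Positive threshold, mm (clinically, 2 mm is the usual
#'   acceptability bound).
#' @return data.frame with `technique`, `method`, `n`, `n_above`,
#'   `proportion`.
#' @export
proportion_above <- function(records, threshold_mm) {
  stopifnot(is.data.frame(records),
            all(c("technique", "method", "tre_mm") %in% names(records)),
            is.numeric(threshold_mm), length(threshold_mm) == 1L,
            threshold_mm > 0)
  key <- interaction(records$technique, records$method, drop = TRUE,
                     sep = "\r")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    rows <- records[key == k, , drop = FALSE]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(technique = parts[1], method = parts[2],
               n = nrow(rows), n_above = sum(rows$tre_mm > threshold_mm),
               proportion = mean(rows$tre_mm > threshold_mm),
               stringsAsFactors = FALSE)
  }))
  out[order(out$technique, out$method), , drop = FALSE]
}

#' Per-group distribution summary of TRE (or sqrt TRE)
#'
#' Histogram (Freedman-Diaconis bins) and Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth) of the error distribution per
#' technique-method group, with skewness of both the raw and square-root
#' scale as normality indices: the square-root transform makes the
#' right-skewed TRE distribution markedly more symmetric.
#'
#' @param records data.frame with `technique`, `method`, `tre_mm`.
#' @param transform `"identity"` (TRE in mm) or `"sqrt"`.
#' @return Named list (one entry per `technique:method` group) of lists with
#'   `n`, `breaks`, `counts`, `mids`, `density` (`x`, `y`, `bw`; `NULL` when
#'   the group has a single record), `skewness` and `skewness_sqrt`.
#' @export
distribution_summary <- function(records, transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(records),
            all(c("technique", "method", "tre_mm") %in% names(records)))
  key <- interaction(records$technique, records$method, drop = TRUE,
                     sep = ":")
  out <- lapply(levels(key), function(k) {
    x_raw <- records$tre_mm[key == k]
    x <- if (transform == "sqrt") sqrt(x_raw) else x_raw
    n_bins <- if (length(x) >= 2L && stats::IQR(x) > 0)
      grDevices::nclass.FD(x) else 1L
    hg <- graphics::hist(x, breaks = max(n_bins, 1L), plot = FALSE)
    dens <- if (length(x) >= 2L && stats::sd(x) > 0) {
      d <- stats::density(x, bw = "nrd0")
      list(x = d$x, y = d$y, bw = d$bw)
    } else NULL
    list(n = length(x), breaks = hg$breaks, counts = hg$counts,
         mids = hg$mids, density = dens,
         skewness = .skewness(x_raw), skewness_sqrt = .skewness(sqrt(x_raw)))
  })
  names(out) <- levels(key)
  out
}

.skewness <- function(x) {
  if (length(x) < 2L || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}
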