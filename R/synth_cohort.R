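# Synthetic cohorts of surface-based morphometry measures: a control
# population with covariate structure and spatially correlated noise,
# MRI-positive patients with implanted FCD-like lesion patches, and
# MRI-negative patients with weak diffuse effects plus lobar hypothesis
# labels built from synthetic parcels.

# The canonical 19 base measures: six morphometric maps, white/grey contrast,
# and T1/FLAIR intensity sampled at six depths along the surface normal
# (75%, 50%, 25% of cortical thickness, white-grey interface, 1 and 2 mm
# subcortically).
MORPH_MEASURES <- c("sulc", "curv", "area", "volume", "thickness", "aici")
T1_MEASURES <- c("t1_75", "t1_50", "t1_25", "t1_interface",
                 "t1_m1mm", "t1_m2mm")
FLAIR_MEASURES <- c("flair_75", "flair_50", "flair_25", "flair_interface",
                    "flair_m1mm", "flair_m2mm")

#' Names of the 19 base surface measures
#'
#' Sulcal depth, mean curvature, area, volume, cortical thickness, absolute
#' intrinsic curvature index, white/grey contrast, and normalized T1 and
#' FLAIR intensity at six cortical/subcortical depths.
#'
#' @return character vector of length 19.
#' @export
sbm_measure_names <- function() {
  c(MORPH_MEASURES, "wg_contrast", T1_MEASURES, FLAIR_MEASURES)
}

# Natural per-vertex scale (SD unit) and baseline of each measure family.
measure_unit_sd <- function(measure) {
  units <- c(sulc = 1, curv = 0.1, area = 0.5, volume = 1, thickness = 0.25,
             aici = 0.1)
  if (measure %in% names(units)) units[[measure]] else 0.06  # intensities
}

morph_baseline <- c(sulc = 0, curv = 0, area = 1, volume = 2.5,
                    thickness = 2.5, aici = 0.1)
t1_depth_mean <- c(t1_75 = 0.10, t1_50 = 0.15, t1_25 = 0.25,
                   t1_interface = 0.55, t1_m1mm = 0.85, t1_m2mm = 0.92)
flair_depth_mean <- c(flair_75 = 0.45, flair_50 = 0.40, flair_25 = 0.38,
                      flair_interface = 0.35, flair_m1mm = 0.30,
                      flair_m2mm = 0.28)

# Smooth, standardized Gaussian random field.
smooth_noise <- function(mesh, fwhm_mm, sd = 1) {
  z <- smooth_field(mesh, rnorm(mesh$nv), fwhm_mm)
  if (sd == 0) return(numeric(mesh$nv))
  (z - mean(z)) / stats::sd(z) * sd
}

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the study conditions of the reference cohort: 94 controls,
#' 5 MRI-positive patients, 27 MRI-negative patients; lesion sizes chosen so
#' that relative lesion areas fall in roughly 0.002-0.016 of the surface, and
#' lobar hypothesis labels covering 0.02-0.36. Lesion effect sizes are in
#' control-SD units with the FCD-like sign profile (thickness up, subcortical
#' T1 down, subcortical FLAIR up; the white/grey contrast decrease emerges
#' from the T1 depth effects because contrast is derived from them).
#'
#' @param n_controls,n_positive,n_negative cohort sizes (controls >= 3).
#' @param n_lesions total number of lesions across MRI-positive subjects
#'   (default one per subject; extras are assigned round-robin).
#' @param lesion_radius_mm range (min, max) of geodesic lesion radii in mm.
#' @param lesion_effects named vector of per-measure effect sizes in
#'   control-SD units; `wg_contrast` may not be set directly (it is derived
#'   from the T1 maps).
#' @param negative_effect_scale multiplier in `[0, 1]` applied to the lesion
#'   profile of MRI-negative subjects' weak diffuse effect.
#' @param hypothesis_phi_range admissible relative area of hypothesis labels.
#' @param noise_sd vertex noise SD in measure-specific units.
#' @param subject_sd SD of the subject-level random intercept.
#' @param spatial_correlation_fwhm_mm FWHM of the smoothing applied to the
#'   vertex noise (gives smooth false-positive structure).
#' @param covariate_effect_sizes named vector (age, sex, site, icv) of
#'   covariate effect sizes in control-SD units per covariate SD; the icv
#'   effect applies only to area, volume and thickness.
#' @param n_parcels_per_hemisphere parcel count for hypothesis labels.
#' @param measures subset of [sbm_measure_names()] to generate (default all
#'   19; `wg_contrast` requires `t1_50` and `t1_m1mm`).
#' @param seed integer seed; generation is fully reproducible.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 94L, n_positive = 5L, n_negative = 27L,
                          n_lesions = NULL,
                          lesion_radius_mm = c(13, 35),
                          lesion_effects = c(thickness = 2,
                                             t1_interface = -1,
                                             t1_m1mm = -1.5, t1_m2mm = -1.5,
                                             flair_m1mm = 2, flair_m2mm = 2),
                          negative_effect_scale = 0.25,
                          hypothesis_phi_range = c(0.02, 0.36),
                          noise_sd = 1, subject_sd = 0.3,
                          spatial_correlation_fwhm_mm = 15,
                          covariate_effect_sizes = c(age = 0.2, sex = 0.1,
                                                     site = 0.2, icv = 0.3),
                          n_parcels_per_hemisphere = 8L,
                          measures = sbm_measure_names(),
                          seed = 1L) {
  if (n_controls < 3) stopf("n_controls must be >= 3")
  n_lesions <- as.integer(n_lesions %||% n_positive)
  if (n_positive > 0 && n_lesions < n_positive)
    stopf("n_lesions must be >= n_positive (every MRI-positive subject needs a lesion)")
  if (length(lesion_radius_mm) != 2 || any(lesion_radius_mm <= 0) ||
      diff(lesion_radius_mm) < 0)
    stopf("lesion_radius_mm must be a valid (min, max) range")
  if ("wg_contrast" %in% names(lesion_effects))
    stopf("wg_contrast is derived from the T1 depth maps; set t1_* effects instead")
  stopifnot(negative_effect_scale >= 0, negative_effect_scale <= 1,
            all(hypothesis_phi_range > 0), all(hypothesis_phi_range < 1),
            noise_sd >= 0, subject_sd >= 0, spatial_correlation_fwhm_mm > 0)
  measures <- match.arg(measures, sbm_measure_names(), several.ok = TRUE)
  if ("wg_contrast" %in% measures &&
      !all(c("t1_50", "t1_m1mm") %in% measures))
    stopf("wg_contrast requires t1_50 and t1_m1mm among the measures")
  structure(list(
    n_controls = as.integer(n_controls), n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative), n_lesions = n_lesions,
    lesion_radius_mm = lesion_radius_mm, lesion_effects = lesion_effects,
    negative_effect_scale = negative_effect_scale,
    hypothesis_phi_range = hypothesis_phi_range,
    noise_sd = noise_sd, subject_sd = subject_sd,
    spatial_correlation_fwhm_mm = spatial_correlation_fwhm_mm,
    covariate_effect_sizes = covariate_effect_sizes,
    n_parcels_per_hemisphere = as.integer(n_parcels_per_hemisphere),
    measures = measures, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Affine intensity normalization against two tissue references
#'
#' Rescales raw scanner-unit intensities so that the cortical reference maps
#' to 0 and the white-matter reference to 1 (a normalized-signal-intensity
#' style two-point map): `out = (raw - cortex_ref) / (wm_ref - cortex_ref)`.
#'
#' @param raw numeric vector of raw intensities.
#' @param wm_reference white-matter reference intensity (e.g. the subject's
#'   median intensity 1 mm subcortically).
#' @param cortex_reference cortical reference intensity (e.g. the median
#'   mid-cortical intensity).
#' @return rescaled numeric vector.
#' @export
normalize_intensity <- function(raw, wm_reference, cortex_reference) {
  if (wm_reference == cortex_reference)
    stopf("wm_reference and cortex_reference must differ (degenerate contrast)")
  (raw - cortex_reference) / (wm_reference - cortex_reference)
}

#' Sample T1 and FLAIR intensity maps at six depths for one subject
#'
#' Given the per-depth modality mean fields (optionally already including
#' covariate effects), adds a per-modality subject intercept, a shared
#' modality noise field and depth-specific noise fields, all spatially
#' correlated. The shared component guarantees an across-depth correlation
#' of at least 0.5 between adjacent depths; the T1 depth means increase
#' monotonically towards the subcortical samples.
#'
#' @param mesh a `surf_mesh`.
#' @param mu_t1,mu_flair matrices (vertices x 6) of per-depth mean fields,
#'   columns named as in [sbm_measure_names()].
#' @param noise_sd,subject_sd,fwhm_mm noise parameters (measure units are
#'   the intensity unit SD).
#' @param shared_frac fraction of noise variance shared across depths of a
#'   modality (default 0.6).
#' @return named list of 12 per-vertex maps (latent normalized-intensity
#'   scale).
#' @export
sample_intensity_depths <- function(mesh, mu_t1, mu_flair, noise_sd = 1,
                                    subject_sd = 0.3, fwhm_mm = 15,
                                    shared_frac = 0.6) {
  unit <- measure_unit_sd("t1_50")
  out <- vector("list", 12L)
  names(out) <- c(T1_MEASURES, FLAIR_MEASURES)
  for (mod in c("t1", "flair")) {
    mu <- if (mod == "t1") mu_t1 else mu_flair
    depths <- if (mod == "t1") T1_MEASURES else FLAIR_MEASURES
    intercept <- rnorm(1, 0, subject_sd * unit)
    shared <- smooth_noise(mesh, fwhm_mm, sqrt(shared_frac) * noise_sd * unit)
    for (d in seq_along(depths)) {
      eps <- smooth_noise(mesh, fwhm_mm,
                          sqrt(1 - shared_frac) * noise_sd * unit)
      out[[depths[d]]] <- mu[, d] + intercept + shared + eps
    }
  }
  out
}

# White/grey contrast as a percent-contrast analog, derived from the
# normalized T1 intensity 1 mm subcortically and at mid-cortex.
wg_contrast_from_t1 <- function(t1_m1mm, t1_50) {
  100 * (t1_m1mm - t1_50) / pmax(0.5 * (t1_m1mm + t1_50), 0.05)
}

# Pick a hypothesis label as a union of 1-3 adjacent parcels within the
# admissible phi range.
pick_hypothesis_label <- function(mesh, parcels, phi_range, max_tries = 40L) {
  ids_of <- function(p) which(parcels %in% p)
  for (i in seq_len(max_tries)) {
    k <- sample(1:3, 1)
    start <- sample(unique(parcels), 1)
    chosen <- start
    while (length(chosen) < k) {
      boundary <- unique(unlist(mesh$adjacency[ids_of(chosen)],
                                use.names = FALSE))
      nb <- setdiff(unique(parcels[boundary]), chosen)
      nb <- nb[(nb > length(unique(parcels)) / 2) ==
                 (start > length(unique(parcels)) / 2)]  # same hemisphere
      if (length(nb) == 0) break
      chosen <- c(chosen, sample(nb, 1))
    }
    phi <- relative_label_size(mesh, ids_of(chosen))
    if (phi >= phi_range[1] && phi <= phi_range[2])
      return(surf_label(mesh, ids_of(chosen), "hypothesis"))
  }
  stopf("could not draw a hypothesis label inside hypothesis_phi_range")
}

#' Generate a synthetic cohort
#'
#' For each generated measure, a subject's map is a smooth population mean
#' field plus linear covariate effects (age, sex, site, and intracranial
#' volume analog for area/volume/thickness), a subject-level random
#' intercept, and spatially correlated vertex noise. MRI-positive subjects
#' receive contiguous geodesic-disc lesions perturbing the measures by the
#' configured effect sizes (FCD-like profile); MRI-negative subjects receive
#' the same profile scaled by `negative_effect_scale` inside a sub-patch of
#' their lobar hypothesis label, which is a union of 1-3 adjacent synthetic
#' parcels. T1/FLAIR maps are generated at six depths with cross-depth
#' correlation, passed through an arbitrary per-subject scanner gain and
#' re-normalized with [normalize_intensity()] using per-subject median
#' references; white/grey contrast is derived deterministically from the
#' normalized T1 maps. Fully reproducible for a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @param mesh a `surf_mesh`.
#' @return object of class `surf_cohort`: fields `mesh`, `subjects` (list of
#'   subject records), `measure_names`, `parcels`, `config`.
#' @export
generate_cohort <- function(config, mesh) {
  stopifnot(inherits(config, "cohort_config"), inherits(mesh, "surf_mesh"))
  if (max(config$lesion_radius_mm) >= pi * mesh$radius / 2)
    stopf("lesion radius exceeds hemisphere size")
  meas <- config$measures
  need_t1 <- any(T1_MEASURES %in% meas) || "wg_contrast" %in% meas
  need_flair <- any(FLAIR_MEASURES %in% meas)
  fwhm <- config$spatial_correlation_fwhm_mm

  with_seed(config$seed, {
    parcels <- build_parcels(mesh, config$n_parcels_per_hemisphere,
                             seed = sample.int(.Machine$integer.max, 1))

    # population mean fields
    mu_morph <- list()
    for (m in intersect(MORPH_MEASURES, meas)) {
      u <- measure_unit_sd(m)
      mu_morph[[m]] <- morph_baseline[[m]] + smooth_noise(mesh, 30, 0.5 * u)
    }
    unit_int <- measure_unit_sd("t1_50")
    pat_t1 <- smooth_noise(mesh, 30, 0.8 * unit_int)
    pat_flair <- smooth_noise(mesh, 30, 0.8 * unit_int)
    mu_t1 <- sapply(T1_MEASURES, function(d) t1_depth_mean[[d]] + pat_t1)
    mu_flair <- sapply(FLAIR_MEASURES,
                       function(d) flair_depth_mean[[d]] + pat_flair)

    # covariate effect spatial patterns (shared across measures)
    covs <- c("age", "sex", "site", "icv")
    pat_cov <- lapply(setNames(covs, covs),
                      function(cv) 1 + smooth_noise(mesh, 40, 0.3))

    groups <- rep(c("control", "mri_positive", "mri_negative"),
                  c(config$n_controls, config$n_positive, config$n_negative))
    n_sub <- length(groups)
    ids <- sprintf("%s%03d", c(control = "ctrl", mri_positive = "pos",
                               mri_negative = "neg")[groups],
                   unlist(lapply(table(factor(groups, unique(groups))),
                                 seq_len)))

    # lesion count per MRI-positive subject (extras round-robin)
    lesions_per <- integer(config$n_positive)
    if (config$n_positive > 0) {
      lesions_per <- rep(1L, config$n_positive)
      extra <- config$n_lesions - config$n_positive
      if (extra > 0)
        lesions_per[rep(seq_len(config$n_positive), length.out = extra)] <-
          lesions_per[rep(seq_len(config$n_positive), length.out = extra)] + 1L
    }

    sd_ref <- function(m) sqrt(config$subject_sd^2 + config$noise_sd^2) *
      measure_unit_sd(m)

    subjects <- vector("list", n_sub)
    pos_i <- 0L
    for (s in seq_len(n_sub)) {
      grp <- groups[s]
      covariates <- list(age = round(runif(1, 20, 60), 1),
                         sex = rbinom(1, 1, 0.5),
                         site = rbinom(1, 1, 0.45),
                         icv_analog = rnorm(1, 1500, 120))
      cov0 <- c(age = (covariates$age - 40) / 12,
                sex = covariates$sex - 0.5,
                site = covariates$site - 0.5,
                icv = (covariates$icv_analog - 1500) / 120)
      cov_field <- function(m) {
        use <- c("age", "sex", "site",
                 if (m %in% c("area", "volume", "thickness")) "icv")
        out <- numeric(mesh$nv)
        for (cv in use) {
          beta <- config$covariate_effect_sizes[[cv]] %||% 0
          if (beta != 0)
            out <- out + beta * cov0[[cv]] * pat_cov[[cv]] * sd_ref(m)
        }
        out
      }

      # latent maps (before lesions / normalization)
      maps <- list()
      for (m in intersect(MORPH_MEASURES, meas)) {
        maps[[m]] <- mu_morph[[m]] + cov_field(m) +
          rnorm(1, 0, config$subject_sd * measure_unit_sd(m)) +
          smooth_noise(mesh, fwhm, config$noise_sd * measure_unit_sd(m))
      }
      if (need_t1 || need_flair) {
        intmaps <- sample_intensity_depths(
          mesh, mu_t1, mu_flair, noise_sd = config$noise_sd,
          subject_sd = config$subject_sd, fwhm_mm = fwhm)
        covi <- cov_field("t1_50")
        for (d in c(if (need_t1) T1_MEASURES, if (need_flair) FLAIR_MEASURES))
          maps[[d]] <- intmaps[[d]] + covi
      }

      # lesions / weak diffuse effects
      lesion_labels <- list()
      hypothesis_label <- NULL
      effect_scale <- switch(grp, mri_positive = 1,
                             mri_negative = config$negative_effect_scale, 0)
      lesion_sets <- list()
      if (grp == "mri_positive") {
        pos_i <- pos_i + 1L
        taken <- integer(0)
        for (l in seq_len(lesions_per[pos_i])) {
          for (try in 1:50) {
            r <- runif(1, config$lesion_radius_mm[1],
                       config$lesion_radius_mm[2])
            lab <- grow_disc_label(mesh, sample.int(mesh$nv, 1), radius_mm = r,
                                   kind = "lesion-strict")
            if (!any(lab$vertex_ids %in% taken)) break
          }
          taken <- c(taken, lab$vertex_ids)
          lesion_labels[[l]] <- lab
          lesion_sets[[l]] <- lab$vertex_ids
        }
      } else if (grp == "mri_negative") {
        hypothesis_label <- pick_hypothesis_label(mesh, parcels,
                                                  config$hypothesis_phi_range)
        r <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
        seedv <- sample(hypothesis_label$vertex_ids, 1)
        patch <- intersect(grow_disc_label(mesh, seedv,
                                           radius_mm = r)$vertex_ids,
                           hypothesis_label$vertex_ids)
        lesion_sets[[1]] <- patch
      }
      if (effect_scale > 0 && length(lesion_sets) > 0) {
        for (m in names(config$lesion_effects)) {
          if (!m %in% names(maps)) next
          delta <- config$lesion_effects[[m]] * sd_ref(m) * effect_scale
          for (vset in lesion_sets)
            maps[[m]][vset] <- maps[[m]][vset] + delta
        }
      }

      # scanner gain and re-normalization of intensities
      for (mod in c(if (need_t1) "t1", if (need_flair) "flair")) {
        depths <- if (mod == "t1") T1_MEASURES else FLAIR_MEASURES
        offset <- rnorm(1, 500, 30)
        scale <- rnorm(1, 600, 30)
        raw <- lapply(maps[depths], function(x) offset + scale * x)
        cortex_ref <- median(raw[[paste0(mod, "_50")]])
        wm_ref <- median(raw[[paste0(mod, "_m1mm")]])
        for (d in depths)
          maps[[d]] <- normalize_intensity(raw[[d]], wm_ref, cortex_ref)
      }
      if ("wg_contrast" %in% meas)
        maps[["wg_contrast"]] <- wg_contrast_from_t1(maps[["t1_m1mm"]],
                                                     maps[["t1_50"]])

      base <- do.call(cbind, maps[intersect(sbm_measure_names(), meas)])
      colnames(base) <- intersect(sbm_measure_names(), meas)
      subjects[[s]] <- list(subject_id = ids[s], group = grp,
                            covariates = covariates,
                            base_measures = base,
                            lesion_labels = lesion_labels,
                            hypothesis_label = hypothesis_label)
    }

    structure(list(mesh = mesh, subjects = subjects,
                   measure_names = intersect(sbm_measure_names(), meas),
                   parcels = parcels, config = config),
              class = "surf_cohort")
  })
}

#' @export
print.surf_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf(paste0("surf_cohort: %d controls, %d MRI-positive, ",
                     "%d MRI-negative; %d measures on %d vertices\n"),
              sum(grp == "control"), sum(grp == "mri_positive"),
              sum(grp == "mri_negative"), length(x$measure_names), x$mesh$nv))
  invisible(x)
}

# convenience accessors
cohort_groups <- function(cohort) vapply(cohort$subjects, `[[`, "", "group")
cohort_ids <- function(cohort) vapply(cohort$subjects, `[[`, "", "subject_id")
cohort_subject <- function(cohort, id) {
  cohort$subjects[[match(id, cohort_ids(cohort))]]
}
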