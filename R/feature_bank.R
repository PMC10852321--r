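# Feature augmentation and standardization: each base measure expands into
# four variants (8 mm smoothed, 32 mm smoothed, difference-of-Gaussians,
# hemispheric asymmetry smoothed at 8 mm), giving 76 features from the
# canonical 19 measures; six named subsets select features for the
# classifiers; a two-stage (per-subject, then per-vertex across controls)
# z-scoring standardizes classifier inputs.

FEATURE_VARIANTS <- c("smooth8", "smooth32", "DoG", "asym8")

#' Build augmented feature banks for every subject
#'
#' For each base measure emits: the 8 mm FWHM smoothed map, the 32 mm
#' smoothed map, their difference (difference-of-Gaussians, a spatial
#' band-pass), and the hemispheric asymmetry (vertex value minus the value at
#' the corresponding contralateral vertex, computed on the raw map and then
#' smoothed at 8 mm). With the canonical 19 measures this yields 76 features.
#'
#' @param cohort a `surf_cohort`.
#' @param fwhm_narrow,fwhm_wide smoothing kernel FWHMs in mm.
#' @return object of class `feature_bank_set`: `banks` (named list of
#'   vertices x features matrices, one per subject), `feature_names`,
#'   `provenance` (data.frame mapping each feature to its (measure, variant)
#'   pair), `measure_names`, `mesh`.
#' @export
augment_features <- function(cohort, fwhm_narrow = 8, fwhm_wide = 32) {
  stopifnot(inherits(cohort, "surf_cohort"))
  mesh <- cohort$mesh
  measures <- cohort$measure_names
  nvh <- mesh$nv_hemi
  contra <- c(seq_len(nvh) + nvh, seq_len(nvh))
  feature_names <- as.vector(t(outer(measures, FEATURE_VARIANTS, paste,
                                     sep = ".")))
  provenance <- data.frame(
    feature = feature_names,
    measure = rep(measures, each = length(FEATURE_VARIANTS)),
    variant = rep(FEATURE_VARIANTS, length(measures)),
    stringsAsFactors = FALSE)

  banks <- lapply(cohort$subjects, function(subj) {
    base <- subj$base_measures
    missing <- setdiff(measures, colnames(base))
    if (length(missing) > 0)
      stopf("subject %s is missing measure(s): %s", subj$subject_id,
            paste(missing, collapse = ", "))
    base <- base[, measures, drop = FALSE]
    s8 <- smooth_field(mesh, base, fwhm_narrow)
    s32 <- smooth_field(mesh, base, fwhm_wide)
    asym <- smooth_field(mesh, base - base[contra, , drop = FALSE],
                         fwhm_narrow)
    out <- matrix(0, mesh$nv, length(feature_names),
                  dimnames = list(NULL, feature_names))
    out[, provenance$variant == "smooth8"] <- s8
    out[, provenance$variant == "smooth32"] <- s32
    out[, provenance$variant == "DoG"] <- s8 - s32
    out[, provenance$variant == "asym8"] <- asym
    out
  })
  names(banks) <- cohort_ids(cohort)
  structure(list(banks = banks, feature_names = feature_names,
                 provenance = provenance, measure_names = measures,
                 mesh = mesh),
            class = "feature_bank_set")
}

#' @export
print.feature_bank_set <- function(x, ...) {
  cat(sprintf("feature_bank_set: %d subjects x %d features (%d measures)\n",
              length(x$banks), length(x$feature_names),
              length(x$measure_names)))
  invisible(x)
}

# The six measures retained in the reduced subset: thickness, white/grey
# contrast, and T1/FLAIR normalized intensity at -1 mm subcortically and at
# 50% of cortical thickness.
REDUCED_MEASURES <- c("thickness", "wg_contrast", "t1_m1mm", "t1_50",
                      "flair_m1mm", "flair_50")

#' Define the six canonical feature subsets
#'
#' `all` (76 features), `base8` (the 19 measures at 8 mm smoothing only,
#' as used for the univariate GLM), `reduced` (6 well-performing measures at
#' all 4 variants = 24 features), and each of the three without any
#' FLAIR-derived feature (`all_noflair`, `base8_noflair`,
#' `reduced_noflair`).
#'
#' @param bank_set a `feature_bank_set` built from the canonical 19 measures.
#' @return named list of 6 character vectors of feature names.
#' @export
define_subsets <- function(bank_set) {
  stopifnot(inherits(bank_set, "feature_bank_set"))
  if (!setequal(bank_set$measure_names, sbm_measure_names()))
    stopf("subsets are defined for banks built from the canonical 19 measures")
  pr <- bank_set$provenance
  sel <- function(measures, variants = FEATURE_VARIANTS)
    pr$feature[pr$measure %in% measures & pr$variant %in% variants]
  no_flair <- setdiff(sbm_measure_names(), FLAIR_MEASURES)
  list(
    all = pr$feature,
    all_noflair = sel(no_flair),
    base8 = sel(sbm_measure_names(), "smooth8"),
    base8_noflair = sel(no_flair, "smooth8"),
    reduced = sel(REDUCED_MEASURES),
    reduced_noflair = sel(setdiff(REDUCED_MEASURES, FLAIR_MEASURES)))
}

#' Two-stage z-scoring of feature banks
#'
#' Stage 1 centers and scales each feature within each subject by its own
#' across-vertex mean and SD (removing subject-level offset and gain);
#' stage 2 centers and scales each feature at each vertex by the
#' across-control mean and SD at that vertex. When the evaluated subject is
#' itself a control, the stage-2 reference excludes it (leave-one-out), so
#' control score maps are not self-contaminated.
#'
#' @param bank_set a `feature_bank_set`.
#' @param control_ids subject ids forming the reference population (>= 3).
#' @param loo logical; if `TRUE` (default) the stage-2 reference excludes the
#'   evaluated subject when it is a control.
#' @return a `feature_bank_set` whose banks are standardized; carries the
#'   `control_ids` used.
#' @export
zscore_features <- function(bank_set, control_ids, loo = TRUE) {
  stopifnot(inherits(bank_set, "feature_bank_set"))
  if (length(control_ids) < 3) stopf("need at least 3 reference subjects")
  if (!all(control_ids %in% names(bank_set$banks)))
    stopf("unknown control ids")

  stage1 <- lapply(bank_set$banks, function(b) {
    mu <- colMeans(b)
    sdv <- apply(b, 2, stats::sd)
    bad <- which(sdv == 0)
    if (length(bad) > 0)
      stopf("zero within-subject SD for feature(s): %s",
            paste(colnames(b)[bad], collapse = ", "))
    sweep(sweep(b, 2, mu), 2, sdv, "/")
  })

  nc <- length(control_ids)
  S <- Reduce(`+`, stage1[control_ids])
  Q <- Reduce(`+`, lapply(stage1[control_ids], function(b) b^2))

  standardize <- function(b, exclude_id) {
    if (loo && !is.null(exclude_id) && exclude_id %in% control_ids) {
      bx <- stage1[[exclude_id]]
      n <- nc - 1
      m <- (S - bx) / n
      v <- (Q - bx^2 - n * m^2) / (n - 1)
    } else {
      n <- nc
      m <- S / n
      v <- (Q - n * m^2) / (n - 1)
    }
    v[v < .Machine$double.eps] <- NA
    out <- (b - m) / sqrt(v)
    out[is.na(out)] <- 0
    out
  }
  banks <- lapply(names(bank_set$banks),
                  function(id) standardize(stage1[[id]], id))
  names(banks) <- names(bank_set$banks)
  out <- bank_set
  out$banks <- banks
  out$stage1 <- stage1
  out$control_ids <- control_ids
  out$standardize_against <- function(id) standardize(stage1[[id]], id)
  out
}
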