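# Vertex-wise single-subject-versus-controls general linear model. Each
# subject is compared to the control population (leave-one-out for controls
# themselves): per vertex, the measure is regressed on nuisance covariates
# over the controls, and the subject's deviation from its covariate-adjusted
# prediction is expressed as a signed z-score with a prediction-variance
# inflation factor, so leave-one-out control z-values are t-distributed (and
# approximately standard normal at the study's control count).

#' Covariate design for the univariate GLM
#'
#' Age, sex and scanner site enter every model; the intracranial-volume
#' analog additionally enters for area, volume and thickness.
#'
#' @param cohort a `surf_cohort`.
#' @return object of class `glm_design` with the covariate matrix and the
#'   per-measure `use_icv` rule.
#' @export
glm_design <- function(cohort) {
  covs <- t(vapply(cohort$subjects, function(s)
    c(age = s$covariates$age, sex = s$covariates$sex,
      site = s$covariates$site, icv_analog = s$covariates$icv_analog),
    numeric(4)))
  rownames(covs) <- cohort_ids(cohort)
  structure(list(covariates = covs,
                 icv_measures = c("area", "volume", "thickness")),
            class = "glm_design")
}

design_matrix <- function(design, ids, measure) {
  X <- cbind(intercept = 1,
             design$covariates[ids, c("age", "sex", "site"), drop = FALSE])
  if (measure %in% design$icv_measures)
    X <- cbind(X, icv = design$covariates[ids, "icv_analog"])
  X
}

#' Vertex-wise GLM z-map for one subject against controls
#'
#' Ordinary least squares of the (smoothed) measure on the covariates over
#' the control set (excluding the subject itself when it is a control);
#' `z = (observed - predicted) / (residual SD * sqrt(1 + x0' (X'X)^-1 x0))`.
#' Positive z means the measure lies above the covariate-adjusted control
#' expectation; the map is used two-tailed downstream.
#'
#' @param subject_id subject to evaluate.
#' @param control_ids reference control ids (the subject is dropped from
#'   this set automatically).
#' @param measure one of the cohort's measure names.
#' @param design a [glm_design()].
#' @param maps matrix (vertices x subjects, columns named by subject id) of
#'   measure maps at the analysis smoothing level.
#' @return object of class `score_map` with `values` (signed z), `method`
#'   `"GLM"`, `two_tailed = TRUE`.
#' @export
subject_zmap <- function(subject_id, control_ids, measure, design, maps) {
  ref <- setdiff(control_ids, subject_id)
  X <- design_matrix(design, ref, measure)
  p <- ncol(X)
  if (length(ref) < p + 2) stopf("need at least %d controls", p + 2)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) stopf("rank-deficient covariate design")
  XtXi <- solve(XtX)
  Y <- maps[, ref, drop = FALSE]
  B <- XtXi %*% crossprod(X, t(Y))            # p x V
  resid <- t(Y) - X %*% B
  s2 <- colSums(resid^2) / (length(ref) - p)
  x0 <- design_matrix(design, subject_id, measure)[1, ]
  mu0 <- as.numeric(x0 %*% B)
  infl <- sqrt(1 + as.numeric(t(x0) %*% XtXi %*% x0))
  se <- sqrt(s2) * infl
  z <- numeric(nrow(maps))
  # vertices with (numerically) zero residual variance get z = 0
  ok <- se > 1e-8 * max(se)
  z[ok] <- (maps[ok, subject_id] - mu0[ok]) / se[ok]
  if (any(!ok))
    warning(sprintf("%d vertices with zero residual SD; z set to 0",
                    sum(!ok)))
  score_map(z, method = "GLM", subject_id = subject_id,
            measure = measure, two_tailed = TRUE, post_smoothed = FALSE)
}

#' GLM z-maps for every subject of a cohort
#'
#' Smooths the base measure once at the analysis FWHM (default 8 mm), then
#' computes the leave-one-out z-map of every subject.
#'
#' @param cohort a `surf_cohort`.
#' @param measure measure name.
#' @param fwhm_mm analysis smoothing (default 8 mm).
#' @param design optional precomputed [glm_design()].
#' @return named list of `score_map` objects, one per subject.
#' @export
glm_zmaps <- function(cohort, measure, fwhm_mm = 8, design = NULL) {
  stopifnot(measure %in% cohort$measure_names)
  design <- design %||% glm_design(cohort)
  ids <- cohort_ids(cohort)
  maps <- vapply(cohort$subjects,
                 function(s) s$base_measures[, measure],
                 numeric(cohort$mesh$nv))
  colnames(maps) <- ids
  maps <- smooth_field(cohort$mesh, maps, fwhm_mm)
  colnames(maps) <- ids
  control_ids <- ids[cohort_groups(cohort) == "control"]
  out <- lapply(ids, function(id)
    subject_zmap(id, control_ids, measure, design, maps))
  names(out) <- ids
  out
}

# ---- score map container ----------------------------------------------------

#' Construct a per-vertex score map
#'
#' Common container for GLM z-maps (signed, used two-tailed) and classifier
#' score maps (Mahalanobis distance >= 0; isolation-forest and
#' random-forest scores in `[0, 1]`, one-tailed).
#'
#' @param values numeric per-vertex statistic (finite).
#' @param method one of "GLM", "MAH", "IF", "RFC".
#' @param subject_id subject identifier.
#' @param measure measure name (GLM) or feature-subset name (classifiers).
#' @param two_tailed logical; thresholding uses `|value|` when TRUE.
#' @param post_smoothed logical; whether 4 mm post-smoothing was applied.
#' @return object of class `score_map`.
#' @export
score_map <- function(values, method, subject_id = NA_character_,
                      measure = NA_character_, two_tailed = FALSE,
                      post_smoothed = FALSE) {
  if (!all(is.finite(values))) stopf("score map contains non-finite values")
  structure(list(values = as.numeric(values), method = method,
                 subject_id = subject_id, measure = measure,
                 two_tailed = two_tailed, post_smoothed = post_smoothed),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("score_map [%s] %s (%s): %d vertices, range [%.3g, %.3g]%s\n",
              x$method, x$subject_id, x$measure, length(x$values),
              min(x$values), max(x$values),
              if (x$two_tailed) ", two-tailed" else ""))
  invisible(x)
}
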