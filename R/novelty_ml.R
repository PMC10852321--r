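# Vertex-wise multivariate scoring: unsupervised novelty detection (robust
# Mahalanobis distance, isolation forest) trained on control vertices only,
# and a supervised random-forest comparator trained on control plus lesional
# vertices with 1:10 class subsampling. Leave-one-out training schedules keep
# the evaluated subject's vertices out of its own model; score maps are
# post-smoothed at 4 mm to suppress small false positives.

#' Robust Mahalanobis novelty model
#'
#' Fits a robust location/scatter estimate (minimum covariance determinant
#' via [MASS::cov.rob()], support fraction `robust_fraction`) on the training
#' vertices and scores new feature vectors by their Mahalanobis distance to
#' the robust mean. The scatter is rescaled so that the median squared
#' training distance matches the chi-square median (consistency at the
#' normal model); squared scores of Gaussian data are then chi-square with
#' `p` degrees of freedom.
#'
#' @param x training matrix (vertices x features).
#' @param robust_fraction MCD support fraction in (0.5, 1], default 0.75.
#' @param max_fit_rows rows are subsampled (seeded) to this cap before the
#'   MCD fit, which is quadratic-ish in n; scoring always uses all data.
#' @param seed integer seed (MCD uses random subset search).
#' @return object of class `novelty_model`, method `"MAH"`.
#' @export
train_mahalanobis <- function(x, robust_fraction = 0.75,
                              max_fit_rows = 20000L, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (nrow(x) < 10 * p)
    stopf("need at least 10 rows per feature to fit a robust scatter")
  with_seed(seed, {
    xf <- x
    if (nrow(xf) > max_fit_rows)
      xf <- xf[sample.int(nrow(xf), max_fit_rows), , drop = FALSE]
    fit <- tryCatch(
      MASS::cov.rob(xf, method = "mcd",
                    quantile.used = floor(robust_fraction * nrow(xf))),
      error = function(e)
        stopf(paste0("robust scatter estimation failed (%s); consider a ",
                     "smaller feature subset"), conditionMessage(e)))
    if (rcond(fit$cov) < 1e-12)
      stopf("singular robust scatter; consider a smaller feature subset")
    d2 <- mahalanobis(xf, fit$center, fit$cov)
    scale <- median(d2) / qchisq(0.5, p)
    cov <- fit$cov * scale
    structure(list(method = "MAH", center = fit$center, cov = cov,
                   cov_inv = solve(cov), features = colnames(x),
                   robust_fraction = robust_fraction),
              class = "novelty_model")
  })
}

#' Isolation-forest novelty model
#'
#' Standard isolation forest with the original algorithm's path-length
#' normalization; anomaly scores lie in `[0, 1]`, higher meaning more
#' anomalous. Defaults are `t = 100` trees and subsampling size
#' `psi = 2048` (large subsamples favor training on normal instances only).
#'
#' @param x training matrix (vertices x features).
#' @param t number of trees.
#' @param psi subsampling size per tree; lowered with a warning when the
#'   training set is smaller.
#' @param seed integer seed.
#' @return object of class `novelty_model`, method `"IF"`.
#' @export
train_isolation_forest <- function(x, t = 100L, psi = 2048L, seed = 1L) {
  x <- as.matrix(x)
  if (psi > nrow(x)) {
    warning(sprintf("psi lowered from %d to the %d available rows",
                    psi, nrow(x)))
    psi <- nrow(x)
  }
  forest <- with_seed(seed, iso_fit(x, as.integer(t), as.integer(psi)))
  structure(list(method = "IF", forest = forest, features = colnames(x),
                 t = t, psi = psi),
            class = "novelty_model")
}

#' Supervised random-forest comparator
#'
#' Binary-class random forest (100 trees, square-root feature sampling,
#' minimum leaf size 1, Gini split criterion) trained on lesional vertices
#' against a random 10x subsample of control vertices (1:10
#' lesional-to-control ratio); the score is the lesional-class probability.
#'
#' @param x_control control training matrix (vertices x features).
#' @param x_lesional lesional training matrix.
#' @param seed integer seed (bagging and the 1:10 subsample).
#' @return object of class `novelty_model`, method `"RFC"`; the training
#'   manifest records the realized class counts.
#' @export
train_rfc <- function(x_control, x_lesional, seed = 1L) {
  x_control <- as.matrix(x_control)
  x_lesional <- as.matrix(x_lesional)
  if (nrow(x_lesional) == 0)
    stopf("no lesional vertices available for supervised training")
  with_seed(seed, {
    n_ctrl <- min(nrow(x_control), 10L * nrow(x_lesional))
    keep <- sample.int(nrow(x_control), n_ctrl)
    dat <- data.frame(rbind(x_lesional, x_control[keep, , drop = FALSE]))
    dat$.class <- factor(rep(c("lesional", "control"),
                             c(nrow(x_lesional), n_ctrl)))
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = dat,
      num.trees = 100, mtry = floor(sqrt(ncol(x_control))),
      min.node.size = 1, splitrule = "gini", probability = TRUE,
      seed = sample.int(.Machine$integer.max, 1), num.threads = 1)
    structure(list(method = "RFC", fit = fit, features = colnames(x_control),
                   n_lesional = nrow(x_lesional), n_control = n_ctrl),
              class = "novelty_model")
  })
}

#' @export
print.novelty_model <- function(x, ...) {
  cat(sprintf("novelty_model [%s], %d features\n", x$method,
              length(x$features)))
  invisible(x)
}

#' Score one subject's feature bank with a fitted model
#'
#' Computes the vertex-wise score (Mahalanobis distance, isolation-forest
#' anomaly score, or lesional-class probability) and smooths the map on the
#' template at 4 mm FWHM. Averaging preserves the score range contracts
#' (MAH stays nonnegative, IF/RFC stay within `[0, 1]`).
#'
#' @param model a `novelty_model`.
#' @param bank standardized feature matrix (vertices x features) of the
#'   evaluated subject; column names must match the model's features.
#' @param mesh a `surf_mesh`.
#' @param fwhm_mm post-smoothing FWHM (default 4 mm; 0 disables).
#' @param subject_id,measure metadata for the returned map.
#' @return a `score_map` (`post_smoothed = TRUE` when smoothing applied).
#' @export
score_subject <- function(model, bank, mesh, fwhm_mm = 4,
                          subject_id = NA_character_,
                          measure = NA_character_) {
  stopifnot(inherits(model, "novelty_model"))
  bank <- as.matrix(bank)
  if (!identical(colnames(bank), model$features))
    stopf("feature names of the bank do not match the model")
  values <- switch(model$method,
    MAH = sqrt(pmax(0, mahalanobis(bank, model$center, model$cov_inv,
                                   inverted = TRUE))),
    IF = iso_score(model$forest, bank),
    RFC = predict(model$fit, data.frame(bank),
                  num.threads = 1)$predictions[, "lesional"],
    stopf("unknown method %s", model$method))
  smoothed <- fwhm_mm > 0
  if (smoothed) values <- smooth_field(mesh, values, fwhm_mm)
  score_map(values, method = model$method, subject_id = subject_id,
            measure = measure, two_tailed = FALSE, post_smoothed = smoothed)
}

#' Leave-one-out training manifests
#'
#' For MAH/IF the training set is all control subjects, minus the evaluated
#' subject when it is itself a control (specificity assessment). For RFC the
#' training set additionally includes the lesional (strict-label) vertices of
#' all MRI-positive subjects, minus the evaluated subject's own data.
#'
#' @param cohort a `surf_cohort`.
#' @param method "MAH", "IF" or "RFC".
#' @return named list (one entry per subject) with `controls` and, for RFC,
#'   `lesional_subjects`.
#' @export
training_schedule <- function(cohort, method = c("MAH", "IF", "RFC")) {
  method <- match.arg(method)
  ids <- cohort_ids(cohort)
  groups <- cohort_groups(cohort)
  control_ids <- ids[groups == "control"]
  if (length(control_ids) < 3) stopf("need at least 3 controls")
  positive_ids <- ids[groups == "mri_positive"]
  out <- lapply(seq_along(ids), function(i) {
    ctrl <- setdiff(control_ids, ids[i])
    if (method == "RFC")
      list(controls = ctrl, lesional_subjects = setdiff(positive_ids, ids[i]))
    else list(controls = ctrl)
  })
  names(out) <- ids
  out
}

# Pool (optionally capped, seeded) training rows from standardized banks.
# Every bank is the subject's own leave-one-out standardization, so the
# evaluated subject never contributes rows or reference statistics to its
# model.
pool_training_rows <- function(std, ids, features, row_cap = 2e6,
                               seed = 1L) {
  mats <- lapply(ids, function(id) std$banks[[id]][, features, drop = FALSE])
  x <- do.call(rbind, mats)
  if (nrow(x) > row_cap)
    x <- with_seed(seed, x[sample.int(nrow(x), row_cap), , drop = FALSE])
  x
}

# Strict-label lesional vertex rows of given MRI-positive subjects.
lesional_rows <- function(cohort, std, subject_ids, features) {
  mats <- lapply(subject_ids, function(id) {
    subj <- cohort_subject(cohort, id)
    ids <- sort(unique(unlist(lapply(subj$lesion_labels, `[[`,
                                     "vertex_ids"))))
    std$banks[[id]][ids, features, drop = FALSE]
  })
  do.call(rbind, mats)
}

#' Score every subject of a cohort with one detector
#'
#' Runs the full leave-one-out schedule: builds (and caches, since all
#' patients share the all-controls training set) one model per distinct
#' training manifest, scores each subject on its own standardized bank, and
#' post-smooths at 4 mm.
#'
#' @param cohort a `surf_cohort`.
#' @param std a standardized `feature_bank_set` from [zscore_features()].
#' @param features character vector of feature names (a subset).
#' @param method "MAH", "IF" or "RFC".
#' @param seed integer seed for the stochastic fits.
#' @param row_cap training-row cap (seeded subsample beyond it).
#' @param ... passed to the trainer (e.g. `psi`, `robust_fraction`).
#' @return named list of `score_map` objects.
#' @export
score_cohort <- function(cohort, std, features, method = c("MAH", "IF",
                                                           "RFC"),
                         seed = 1L, row_cap = 2e6, ...) {
  method <- match.arg(method)
  schedule <- training_schedule(cohort, method)
  mesh <- cohort$mesh
  cache <- new.env(parent = emptyenv())
  maps <- lapply(names(schedule), function(id) {
    man <- schedule[[id]]
    ref_key <- paste(c(man$controls, man$lesional_subjects %||% character()),
                     collapse = ",")
    model <- if (exists(ref_key, envir = cache, inherits = FALSE)) {
      get(ref_key, envir = cache)
    } else {
      x_ctrl <- pool_training_rows(std, man$controls, features, row_cap,
                                   seed)
      m <- switch(method,
        MAH = train_mahalanobis(x_ctrl, seed = seed, ...),
        IF = train_isolation_forest(x_ctrl, seed = seed, ...),
        RFC = train_rfc(x_ctrl,
                        lesional_rows(cohort, std, man$lesional_subjects,
                                      features),
                        seed = seed, ...))
      assign(ref_key, m, envir = cache)
      m
    }
    score_subject(model, std$banks[[id]][, features, drop = FALSE], mesh,
                  subject_id = id, measure = paste(method, "bank"))
  })
  names(maps) <- names(schedule)
  maps
}
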