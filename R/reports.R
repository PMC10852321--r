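# Experiment orchestration: generate a cohort, run the requested detectors,
# evaluate AFROC performance of the MRI-positive cohort (against wide lesion
# labels) and the MRI-negative cohort (against hypothesis labels), each with
# its own Monte-Carlo guessing null, and write CSV/JSON reports.

#' Experiment configuration
#'
#' @param cohort a [cohort_config()].
#' @param glm_measures measures to analyse univariately (default: cortical
#'   thickness).
#' @param ml_methods multivariate detectors to run, subset of
#'   `c("MAH", "IF", "RFC")`.
#' @param subsets feature-subset names (see [define_subsets()]) for the
#'   multivariate detectors.
#' @param n_thresholds AFROC threshold-grid size.
#' @param m_null Monte-Carlo guessing runs per null distribution.
#' @param bonferroni_k family size for the adjusted p-values (default: the
#'   number of conditions evaluated per cohort).
#' @param wide_dilation dilation rounds turning strict lesion labels into
#'   the wide evaluation version.
#' @param seed integer master seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              glm_measures = "thickness",
                              ml_methods = character(),
                              subsets = "reduced",
                              n_thresholds = 128L,
                              m_null = 2000L,
                              bonferroni_k = NULL,
                              wide_dilation = 4L,
                              seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  ml_methods <- if (length(ml_methods))
    match.arg(ml_methods, c("MAH", "IF", "RFC"), several.ok = TRUE)
  else character()
  structure(list(cohort = cohort, glm_measures = glm_measures,
                 ml_methods = ml_methods, subsets = subsets,
                 n_thresholds = as.integer(n_thresholds),
                 m_null = as.integer(m_null), bonferroni_k = bonferroni_k,
                 wide_dilation = as.integer(wide_dilation),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Evaluation labels of one cohort arm.
arm_labels <- function(cohort, arm, wide_dilation) {
  mesh <- cohort$mesh
  groups <- cohort_groups(cohort)
  ids <- cohort_ids(cohort)
  if (arm == "mri_positive") {
    sel <- which(groups == "mri_positive")
    labels <- lapply(sel, function(i)
      lapply(cohort$subjects[[i]]$lesion_labels, function(l)
        dilate_label(mesh, l, wide_dilation, kind = "lesion-wide")))
  } else {
    sel <- which(groups == "mri_negative")
    labels <- lapply(sel, function(i)
      list(cohort$subjects[[i]]$hypothesis_label))
  }
  names(labels) <- ids[sel]
  labels[lengths(labels) > 0]
}

evaluate_condition <- function(maps, labels, control_ids, mesh, grid_n,
                               null) {
  grid <- threshold_grid(maps[c(names(labels), control_ids)], grid_n)
  curve <- afroc_curve(maps, labels, control_ids, mesh, grid,
                       compute_fpr = TRUE)
  p <- mc_p_value(curve$auc, null)
  list(curve = curve, auc = curve$auc, p = p)
}

#' Run a full detection experiment
#'
#' Generates the cohort, runs every requested detector (univariate GLM per
#' measure; MAH/IF/RFC per feature subset), evaluates each on the
#' MRI-positive arm (wide lesion labels) and the MRI-negative arm
#' (hypothesis labels) with a Monte-Carlo guessing null per arm, applies
#' Bonferroni control across the conditions of each arm, and collects a
#' per-lesion significance table.
#'
#' @param config an [experiment_config()].
#' @param mesh a `surf_mesh`.
#' @return list of class `experiment_result` with `auc_table` (one row per
#'   method x subset x arm), `per_lesion` (one row per label), `nulls`,
#'   `curves`, `config`, and provenance.
#' @export
run_experiment <- function(config, mesh) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(mesh, "surf_mesh"))
  cohort <- generate_cohort(config$cohort, mesh)
  ids <- cohort_ids(cohort)
  groups <- cohort_groups(cohort)
  control_ids <- ids[groups == "control"]

  arms <- list()
  for (arm in c("mri_positive", "mri_negative")) {
    labels <- arm_labels(cohort, arm, config$wide_dilation)
    if (length(labels) == 0) next
    flat <- unlist(labels, recursive = FALSE)
    subj_of <- rep(seq_along(labels), lengths(labels))
    null <- null_auc_distribution(mesh, flat, length(control_ids),
                                  m = config$m_null,
                                  seed = config$seed + 101L,
                                  label_subjects = subj_of)
    arms[[arm]] <- list(labels = labels, null = null)
  }
  if (length(arms) == 0) stopf("cohort has no labelled patients to evaluate")

  conditions <- list()   # name -> maps
  if (length(config$glm_measures) > 0) {
    design <- glm_design(cohort)
    for (meas in config$glm_measures)
      conditions[[paste0("GLM.", meas)]] <-
        glm_zmaps(cohort, meas, design = design)
  }
  if (length(config$ml_methods) > 0) {
    bank <- augment_features(cohort)
    std <- zscore_features(bank, control_ids)
    subset_defs <- if (setequal(cohort$measure_names, sbm_measure_names()))
      define_subsets(bank)
    else list(all = bank$feature_names)
    for (method in config$ml_methods) {
      for (ss in config$subsets) {
        feats <- subset_defs[[ss]]
        if (is.null(feats))
          stopf("unknown feature subset '%s' for this cohort", ss)
        conditions[[paste0(method, ".", ss)]] <-
          score_cohort(cohort, std, feats, method,
                       seed = config$seed + 202L)
      }
    }
  }

  rows <- list()
  curves <- list()
  per_lesion <- list()
  for (cond in names(conditions)) {
    maps <- conditions[[cond]]
    for (arm in names(arms)) {
      ev <- evaluate_condition(maps, arms[[arm]]$labels, control_ids, mesh,
                               config$n_thresholds, arms[[arm]]$null)
      rows[[paste(cond, arm)]] <- data.frame(
        condition = cond, arm = arm, auc = ev$auc, p = ev$p,
        stringsAsFactors = FALSE)
      curves[[paste(cond, arm)]] <- ev$curve
      # per-lesion significance
      lab_tab <- ev$curve$labels
      grid <- ev$curve$points$threshold
      fpf_at <- function(k) if (is.finite(k)) ev$curve$points$FPF[k] else 1
      per_lesion[[paste(cond, arm)]] <- data.frame(
        condition = cond, arm = arm, label = lab_tab$label,
        phi = lab_tab$phi,
        fpf_detection = vapply(lab_tab$detect_idx, fpf_at, 0),
        detected = is.finite(lab_tab$detect_idx),
        stringsAsFactors = FALSE)
    }
  }
  auc_table <- do.call(rbind, rows)
  rownames(auc_table) <- NULL
  k <- config$bonferroni_k %||% length(conditions)
  auc_table$p_adjusted <- bonferroni_adjust(auc_table$p, k = k)
  per_lesion <- do.call(rbind, per_lesion)
  rownames(per_lesion) <- NULL
  per_lesion$p_lesion <- per_lesion_null_probability(
    per_lesion$fpf_detection, per_lesion$phi)

  structure(list(
    auc_table = auc_table, per_lesion = per_lesion,
    nulls = lapply(arms, `[[`, "null"), curves = curves,
    config = config,
    provenance = list(r_version = R.version.string,
                      package_version =
                        as.character(utils::packageVersion("surflesion")),
                      seed = config$seed,
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result\n")
  print(x$auc_table)
  invisible(x)
}

#' Write experiment reports to disk
#'
#' Emits `auc_table.csv` (AUC, p and Bonferroni-adjusted p per condition and
#' arm), `per_lesion.csv` (one row per lesion/hypothesis label with its phi,
#' FPF at detection and per-lesion null probability), one
#' `null_<arm>.csv` of AUC samples per arm, and `provenance.json` (seeds,
#' versions, parameters). All outputs are regenerable from the config and
#' seed alone.
#'
#' @param result an `experiment_result`.
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_reports <- function(result, outdir) {
  stopifnot(inherits(result, "experiment_result"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0)
    stopf("cannot write to directory '%s'", outdir)
  files <- character(0)
  f <- file.path(outdir, "auc_table.csv")
  write.csv(result$auc_table, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, "per_lesion.csv")
  write.csv(result$per_lesion, f, row.names = FALSE)
  files <- c(files, f)
  for (arm in names(result$nulls)) {
    f <- file.path(outdir, sprintf("null_%s.csv", arm))
    write.csv(data.frame(auc = result$nulls[[arm]]$auc_samples), f,
              row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(outdir, "provenance.json")
  prov <- result$provenance
  prov$cohort_config <- result$config$cohort[
    setdiff(names(result$config$cohort), "measures")]
  prov$measures <- result$config$cohort$measures
  jsonlite::write_json(prov, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
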