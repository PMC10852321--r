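# Plain-text export of per-vertex maps and whole cohorts: one value per
# line for maps, one directory per subject for cohorts, with a JSON config
# recording every generation parameter and seed.

#' Write a per-vertex map as plain text
#'
#' One value per line in full precision; readable by any tool.
#'
#' @param values numeric vector, or a `score_map`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_vertex_map <- function(values, path) {
  if (inherits(values, "score_map")) values <- values$values
  writeLines(sprintf("%.17g", values), path)
  invisible(path)
}

#' Read a per-vertex map written by [write_vertex_map()]
#' @param path input file path.
#' @return numeric vector.
#' @export
read_vertex_map <- function(path) {
  as.numeric(readLines(path))
}

#' Serialize a cohort to a directory tree
#'
#' Writes one sub-directory per subject containing a plain-text map per
#' measure and the subject's labels as vertex-index files, plus
#' `covariates.csv` (one row per subject) and `config.json` documenting
#' every generation parameter and seed, so the cohort is regenerable and
#' inspectable outside R.
#'
#' @param cohort a `surf_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "surf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  covs <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               age = s$covariates$age, sex = s$covariates$sex,
               site = s$covariates$site,
               icv_analog = s$covariates$icv_analog)))
  write.csv(covs, file.path(dir, "covariates.csv"), row.names = FALSE)
  for (s in cohort$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (meas in colnames(s$base_measures))
      write_vertex_map(s$base_measures[, meas],
                       file.path(sdir, paste0(meas, ".txt")))
    for (li in seq_along(s$lesion_labels))
      write_surface_label(s$lesion_labels[[li]],
                          file.path(sdir, sprintf("lesion_%02d.label", li)))
    if (!is.null(s$hypothesis_label))
      write_surface_label(s$hypothesis_label,
                          file.path(sdir, "hypothesis.label"))
  }
  cfg <- cohort$config
  jsonlite::write_json(cfg[setdiff(names(cfg), NULL)],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
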