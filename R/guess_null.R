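# The random-guessing null hypothesis for AFROC evaluation: closed-form
# curve and AUC for a guessing process placing marks uniformly over the
# cortical surface, finite-cohort Monte-Carlo null distributions of the
# AFROC AUC, permutation-style p-values p = (b + 1) / (m + 1), Bonferroni
# control, and per-lesion detection significance.

check_unit <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("%s must lie in [0, 1]", name)
  x
}

#' Closed-form guessing TPF at a given FPF
#'
#' For a guessing process marking vertices uniformly at random, the expected
#' AFROC curve for ground-truth labels of relative size `phi` is
#' `TPF = 1 - (1 - FPF)^phi` (the large-cohort limit).
#'
#' @param fpf false positive fraction in `[0, 1]` (vectorized).
#' @param phi relative label size in `[0, 1]`.
#' @return TPF value(s).
#' @export
closed_form_tpf <- function(fpf, phi) {
  check_unit(fpf, "fpf"); check_unit(phi, "phi")
  1 - (1 - fpf)^phi
}

#' Closed-form guessing AFROC AUC
#'
#' Integrating `1 - (1 - FPF)^phi` over FPF in `[0, 1]` gives
#' `AUC = phi / (phi + 1)`: 0.5 when labels cover the whole surface (the
#' task degenerates to binary classification) and tending to 0 as labels
#' shrink.
#'
#' @param phi relative label size in `[0, 1]` (vectorized).
#' @return AUC value(s) in `[0, 0.5]`.
#' @export
closed_form_auc <- function(phi) {
  check_unit(phi, "phi")
  phi / (phi + 1)
}

#' One Monte-Carlo guessing run
#'
#' Every subject (patients and controls) receives `N ~ Poisson(lambda_max)`
#' marks at uniformly random vertices, each with an independent activation
#' level `u ~ U(0, 1)`. The operating point at level `l` uses the marks with
#' `u <= l` — a marking process of rate `l * lambda_max`, monotonically
#' coupled across levels, whose expected curve is exactly the closed form
#' `TPF = 1 - (1 - FPF)^phi`. A label is detected at level `l` when at least
#' one active mark falls inside it; a control is flagged when it has any
#' active mark. The AUC uses the same trapezoid/closure rule as
#' [afroc_curve()].
#'
#' @param mesh a `surf_mesh` (marks are uniform over its vertices).
#' @param labels list of `surf_label` ground-truth labels.
#' @param n_controls number of control subjects.
#' @param lambda_max Poisson mean of marks per subject at the loosest level.
#' @param n_levels number of activation levels in the sweep.
#' @param label_subjects optional integer grouping: labels with the same
#'   value belong to one patient and share that patient's marks (default:
#'   one patient per label).
#' @return list with `auc`, `tpf`, `fpf`, `levels`.
#' @export
simulate_guessing_run <- function(mesh, labels, n_controls,
                                  lambda_max = 20, n_levels = 256L,
                                  label_subjects = NULL) {
  if (length(labels) == 0) stopf("labels must be non-empty")
  if (n_controls < 1) stopf("need at least one control")
  label_subjects <- label_subjects %||% seq_along(labels)
  stopifnot(length(label_subjects) == length(labels))
  n_pat <- max(label_subjects)
  nv <- mesh$nv

  # patient marks: detection level of each label = min activation level of
  # the patient's marks inside it
  det <- rep(Inf, length(labels))
  for (s in seq_len(n_pat)) {
    n_marks <- rpois(1, lambda_max)
    if (n_marks == 0) next
    verts <- sample.int(nv, n_marks, replace = TRUE)
    u <- runif(n_marks)
    for (li in which(label_subjects == s)) {
      inside <- u[verts %in% labels[[li]]$vertex_ids]
      if (length(inside)) det[li] <- min(inside)
    }
  }
  # control flag level = min of N uniforms ~ Beta(1, N): exact inverse cdf
  n_c <- rpois(n_controls, lambda_max)
  ctrl <- ifelse(n_c > 0, 1 - (1 - runif(n_controls))^(1 / pmax(n_c, 1)), Inf)

  levels <- seq_len(n_levels) / n_levels
  sd_det <- sort(det[is.finite(det)])
  sd_ctrl <- sort(ctrl[is.finite(ctrl)])
  tpf <- findInterval(levels, sd_det) / length(labels)
  fpf <- findInterval(levels, sd_ctrl) / n_controls
  list(auc = afroc_auc_from_points(fpf, tpf), tpf = tpf, fpf = fpf,
       levels = levels)
}

#' Monte-Carlo null distribution of the AFROC AUC
#'
#' Repeats [simulate_guessing_run()] `m` times for the given label set and
#' control count; the resulting AUC samples form the null distribution
#' against which an observed detection AUC is tested.
#'
#' @inheritParams simulate_guessing_run
#' @param m number of simulation runs.
#' @param seed integer seed (reproducible).
#' @return object of class `null_dist`: `auc_samples`, `m` and a cohort
#'   manifest (label phis, counts, parameters, seed).
#' @export
null_auc_distribution <- function(mesh, labels, n_controls, m = 1e4L,
                                  seed = 1L, lambda_max = 20,
                                  n_levels = 256L, label_subjects = NULL) {
  if (m < 1) stopf("m must be >= 1")
  samples <- with_seed(seed, vapply(seq_len(m), function(i)
    simulate_guessing_run(mesh, labels, n_controls, lambda_max, n_levels,
                          label_subjects)$auc, 0))
  structure(list(
    auc_samples = samples, m = as.integer(m),
    manifest = list(phi = vapply(labels, `[[`, 0, "phi"),
                    n_labels = length(labels), n_controls = n_controls,
                    lambda_max = lambda_max, n_levels = n_levels,
                    seed = seed)),
    class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf(paste0("null_dist: m = %d guessing runs, %d labels ",
                     "(mean phi %.4g), %d controls; mean AUC = %.4g\n"),
              x$m, x$manifest$n_labels, mean(x$manifest$phi),
              x$manifest$n_controls, mean(x$auc_samples)))
  invisible(x)
}

#' Monte-Carlo p-value of an observed AFROC AUC
#'
#' `p = (b + 1) / (m + 1)` where `b` counts null samples greater than or
#' equal to the observed AUC (one-sided; ties count against the observation,
#' conservative). With `m = 1e5` runs the smallest attainable p-value is
#' about 1e-5.
#'
#' @param observed_auc observed AFROC AUC (or an `afroc_curve`).
#' @param null a `null_dist`.
#' @return p-value in `(0, 1]`.
#' @export
mc_p_value <- function(observed_auc, null) {
  stopifnot(inherits(null, "null_dist"))
  if (inherits(observed_auc, "afroc_curve")) observed_auc <- observed_auc$auc
  b <- sum(null$auc_samples >= observed_auc)
  (b + 1) / (null$m + 1)
}

#' Bonferroni adjustment
#'
#' `min(1, k * p)` per entry, a conservative family-wise error control over
#' `k` comparisons (the number of detection conditions tested).
#'
#' @param p_values numeric vector of p-values.
#' @param k family size (default the number of p-values).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, k = length(p_values)) {
  check_unit(p_values, "p_values")
  if (k < 1) stopf("k must be >= 1")
  pmin(1, k * p_values)
}

#' Per-lesion detection probability under the guessing null
#'
#' Probability that a label of relative size `phi` would be detected by the
#' guessing process at an operating point with the given FPF:
#' `P = 1 - (1 - FPF_detection)^phi`. Used as a per-lesion p-value for the
#' FPF at the strictest threshold that detects the lesion (small = the
#' lesion is found earlier than guessing would).
#'
#' @param fpf_detection FPF at the strictest detecting threshold, in
#'   `[0, 1]`.
#' @param phi relative label size in `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
per_lesion_null_probability <- function(fpf_detection, phi) {
  check_unit(fpf_detection, "fpf_detection")
  check_unit(phi, "phi")
  1 - (1 - fpf_detection)^phi
}
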