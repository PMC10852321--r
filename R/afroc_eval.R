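# AFROC evaluation: threshold sweeps over score/z maps, clustering of
# suprathreshold vertices, the centroid-in-label detection criterion, and
# operating points (TPF, FPF, FPR) integrated into the alternative
# free-response ROC area. False positives are counted in control subjects
# only (patients may harbour additional true lesions).

map_stat <- function(map) {
  if (inherits(map, "score_map")) {
    if (map$two_tailed) abs(map$values) else map$values
  } else as.numeric(map)
}

#' Pooled-quantile threshold grid
#'
#' Thresholds are empirical quantiles of the detection statistic (`|z|` for
#' two-tailed maps, the raw score otherwise), ordered from strict (high) to
#' lenient (low). Half of the grid is spent on quantiles of the pooled
#' vertex values (the background sweep), the other half on quantiles of the
#' per-subject map maxima: the latter is where the operating points actually
#' move, because a subject contributes its first cluster exactly when the
#' threshold crosses its map maximum. All grid values are observed map
#' values (type-1 quantiles).
#'
#' @param maps list of `score_map` objects (or numeric vectors).
#' @param n_thresholds number of thresholds (default 512).
#' @return decreasing numeric vector (may be shorter than requested after
#'   deduplication).
#' @export
threshold_grid <- function(maps, n_thresholds = 512L) {
  if (length(maps) == 0) stopf("no maps supplied")
  stats <- lapply(maps, map_stat)
  pooled <- unlist(stats, use.names = FALSE)
  if (max(pooled) == min(pooled))
    stopf("all maps are constant; no threshold sweep possible")
  n1 <- max(1L, n_thresholds %/% 2L)
  probs1 <- seq(0, 1, length.out = n1 + 2L)[-c(1L, n1 + 2L)]
  # drop the floor value so a zero-inflated background (sparse maps) does
  # not swallow the whole background sweep
  body_pool <- pooled[pooled > min(pooled)]
  g1 <- quantile(body_pool, probs = probs1, type = 1, names = FALSE)
  n2 <- n_thresholds - n1
  g2 <- if (n2 > 0) {
    maxima <- vapply(stats, max, 0)
    tail_pool <- pooled[pooled >= min(maxima)]
    quantile(tail_pool, probs = seq(0, 1, length.out = n2), type = 1,
             names = FALSE)
  } else numeric(0)
  sort(unique(c(g1, g2)), decreasing = TRUE)
}

#' Extract detection marks at one threshold
#'
#' Thresholds the map (`|value| >= tau` for two-tailed maps, `value >= tau`
#' otherwise), clusters suprathreshold vertices into connected components
#' and reduces each cluster to a mark at its area-weighted centroid vertex.
#'
#' @param map a `score_map` or numeric vector.
#' @param mesh a `surf_mesh`.
#' @param threshold scalar threshold.
#' @param two_tailed used when `map` is a bare numeric vector.
#' @return list of marks, each with `centroid`, `cluster`, `threshold`.
#' @export
extract_marks <- function(map, mesh, threshold, two_tailed = FALSE) {
  stat <- if (inherits(map, "score_map")) map_stat(map)
          else if (two_tailed) abs(as.numeric(map)) else as.numeric(map)
  comps <- connected_components(mesh, stat >= threshold)
  lapply(comps, function(cl)
    list(centroid = cluster_centroid(mesh, cl), cluster = cl,
         threshold = threshold))
}

#' Rate marks against ground-truth labels
#'
#' A label counts as detected when at least one mark centroid lies inside it
#' (the strict centroid criterion: a cluster overlapping the label but with
#' its centroid outside does not count). Marks in patients contribute to no
#' false-positive tally; only control marks do.
#'
#' @param marks_by_subject named list (subject id -> list of marks from
#'   [extract_marks()]).
#' @param labels_by_subject named list (patient id -> list of `surf_label`).
#' @param control_ids character vector of control subject ids.
#' @return list with `detected` (logical per label, names `subject:index`),
#'   `fp_clusters` (integer per control), `fpf`, `fpr`, `tpf`.
#' @export
rate_marks <- function(marks_by_subject, labels_by_subject, control_ids) {
  detected <- logical(0)
  for (sid in names(labels_by_subject)) {
    marks <- marks_by_subject[[sid]] %||% list()
    centroids <- vapply(marks, `[[`, 0L, "centroid")
    labs <- labels_by_subject[[sid]]
    for (li in seq_along(labs)) {
      det <- any(centroids %in% labs[[li]]$vertex_ids)
      detected[paste0(sid, ":", li)] <- det
    }
  }
  fp <- vapply(control_ids, function(sid)
    length(marks_by_subject[[sid]] %||% list()), 0L)
  list(detected = detected, fp_clusters = fp,
       tpf = if (length(detected)) mean(detected) else NA_real_,
       fpf = if (length(fp)) mean(fp > 0) else NA_real_,
       fpr = if (length(fp)) mean(fp) else NA_real_)
}

# First (strictest) grid index at which each label is detected (Inf if
# never), plus per-control first-cluster threshold index and cluster counts.
sweep_detections <- function(maps, labels_by_subject, control_ids, grid,
                             mesh, compute_fpr = TRUE) {
  patient_ids <- names(labels_by_subject)
  label_names <- character(0)
  label_phi <- numeric(0)
  detect_idx <- numeric(0)
  for (sid in patient_ids) {
    stat <- map_stat(maps[[sid]])
    labs <- labels_by_subject[[sid]]
    first <- rep(Inf, length(labs))
    for (k in seq_along(grid)) {
      if (all(is.finite(first))) break
      if (max(stat) < grid[k]) next
      comps <- connected_components(mesh, stat >= grid[k])
      if (length(comps) == 0) next
      centroids <- vapply(comps, function(cl) cluster_centroid(mesh, cl), 0L)
      for (li in seq_along(labs)) {
        if (is.finite(first[li])) next
        if (any(centroids %in% labs[[li]]$vertex_ids)) first[li] <- k
      }
    }
    label_names <- c(label_names, paste0(sid, ":", seq_along(labs)))
    label_phi <- c(label_phi, vapply(labs, `[[`, 0, "phi"))
    detect_idx <- c(detect_idx, first)
  }
  # control first-exceedance index: FPF needs only the map maximum
  ctrl_max <- vapply(control_ids, function(sid) max(map_stat(maps[[sid]])), 0)
  ctrl_first <- vapply(ctrl_max, function(mx) {
    k <- which(grid <= mx)
    if (length(k)) k[1] else Inf
  }, 0)
  fpr <- NULL
  if (compute_fpr) {
    fpr <- matrix(0, length(control_ids), length(grid),
                  dimnames = list(control_ids, NULL))
    for (ci in seq_along(control_ids)) {
      stat <- map_stat(maps[[control_ids[ci]]])
      for (k in seq_along(grid)) {
        if (max(stat) < grid[k]) next
        fpr[ci, k] <- length(connected_components(mesh, stat >= grid[k]))
      }
    }
  }
  list(label_names = label_names, label_phi = label_phi,
       detect_idx = detect_idx, ctrl_first = ctrl_first, fpr = fpr)
}

afroc_auc_from_points <- function(fpf, tpf) {
  # close the curve: prepend (0, 0), integrate by trapezoid over FPF, and
  # extend horizontally at the final TPF to FPF = 1
  fpf <- c(0, fpf)
  tpf <- c(0, tpf)
  auc <- sum(diff(fpf) * (head(tpf, -1) + tpf[-1]) / 2)
  auc + (1 - fpf[length(fpf)]) * tpf[length(tpf)]
}

#' AFROC curve and AUC for a cohort of maps
#'
#' Sweeps the threshold grid from strict to lenient; at each threshold the
#' true positive fraction is the fraction of ground-truth labels detected at
#' that or any stricter threshold (detection is monotone in leniency), the
#' false positive fraction is the fraction of control subjects with any
#' suprathreshold cluster, and the false positive rate is the mean cluster
#' count in controls. The AUC integrates TPF over FPF in `[0, 1]` with the
#' curve closed at (0, 0) and extended horizontally to FPF = 1.
#'
#' @param maps named list of `score_map` objects for all subjects.
#' @param labels_by_subject named list (patient id -> list of `surf_label`);
#'   use wide lesion labels or hypothesis labels as appropriate.
#' @param control_ids control subject ids.
#' @param mesh a `surf_mesh`.
#' @param grid threshold grid (default [threshold_grid()] of the maps).
#' @param compute_fpr set FALSE to skip the per-threshold cluster counts in
#'   controls (FPR column reported as NA), which dominates runtime.
#' @return object of class `afroc_curve`: `points` (data.frame threshold,
#'   TPF, FPF, FPR), `auc`, `labels` (names and phi), `n_controls`.
#' @export
afroc_curve <- function(maps, labels_by_subject, control_ids, mesh,
                        grid = NULL, compute_fpr = TRUE) {
  if (length(labels_by_subject) == 0) stopf("need at least one label")
  if (length(control_ids) == 0) stopf("need at least one control")
  grid <- grid %||% threshold_grid(maps)
  sw <- sweep_detections(maps, labels_by_subject, control_ids, grid, mesh,
                         compute_fpr)
  ks <- seq_along(grid)
  tpf <- vapply(ks, function(k) mean(sw$detect_idx <= k), 0)
  fpf <- vapply(ks, function(k) mean(sw$ctrl_first <= k), 0)
  fpr <- if (is.null(sw$fpr)) rep(NA_real_, length(ks))
         else colMeans(sw$fpr)
  structure(list(
    points = data.frame(threshold = grid, TPF = tpf, FPF = fpf, FPR = fpr),
    auc = afroc_auc_from_points(fpf, tpf),
    labels = data.frame(label = sw$label_names, phi = sw$label_phi,
                        detect_idx = sw$detect_idx),
    n_controls = length(control_ids)),
    class = "afroc_curve")
}

#' @export
print.afroc_curve <- function(x, ...) {
  cat(sprintf("afroc_curve: AUC = %.4f (%d labels, %d controls, %d thresholds)\n",
              x$auc, nrow(x$labels), x$n_controls, nrow(x$points)))
  invisible(x)
}

#' Plot an AFROC curve
#' @param x an `afroc_curve`.
#' @param ... passed to [plot()].
#' @export
plot.afroc_curve <- function(x, ...) {
  fpf <- c(0, x$points$FPF, 1)
  tpf <- c(0, x$points$TPF, x$points$TPF[nrow(x$points)])
  plot(fpf, tpf, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "FPF", ylab = "TPF",
       main = sprintf("AFROC (AUC = %.3f)", x$auc), ...)
  invisible(x)
}

#' FPF at the strictest threshold detecting one label
#'
#' Finds the strictest grid threshold at which the given label is detected
#' (centroid criterion) and returns the cohort FPF at that threshold; labels
#' never detected over the sweep return FPF 1 with `detected = FALSE`.
#' Feeding this FPF into [per_lesion_null_probability()] gives the
#' per-lesion significance under the guessing null.
#'
#' @param maps named list of `score_map` objects (must include the patient
#'   and the controls).
#' @param patient_id subject owning the label.
#' @param label a `surf_label`.
#' @param control_ids control subject ids.
#' @param mesh a `surf_mesh`.
#' @param grid threshold grid.
#' @return list with `fpf_detection`, `detected`, `threshold`.
#' @export
per_lesion_detection_fpf <- function(maps, patient_id, label, control_ids,
                                     mesh, grid = NULL) {
  if (length(label$vertex_ids) == 0) stopf("empty label")
  grid <- grid %||% threshold_grid(maps)
  sw <- sweep_detections(maps, setNames(list(list(label)), patient_id),
                         control_ids, grid, mesh, compute_fpr = FALSE)
  k <- sw$detect_idx[1]
  if (!is.finite(k))
    return(list(fpf_detection = 1, detected = FALSE, threshold = NA_real_))
  list(fpf_detection = mean(sw$ctrl_first <= k), detected = TRUE,
       threshold = grid[k])
}
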