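# Brute-force reference implementations, independent of the package's
# clustering and curve code: components via igraph, centroids and AFROC
# accounting written directly from the definitions.

oracle_components <- function(mesh, mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  e <- mesh$edges
  keep <- mask[e[, 1]] & mask[e[, 2]]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (any(keep)) {
    el <- cbind(match(e[keep, 1], idx), match(e[keep, 2], idx))
    g <- igraph::add_edges(g, t(el))
  }
  memb <- igraph::components(g)$membership
  comps <- unname(split(idx, memb))
  comps[order(vapply(comps, min, 0))]
}

oracle_centroid <- function(mesh, cluster) {
  cluster <- sort(as.integer(cluster))
  w <- mesh$vertex_area[cluster]
  xyz <- mesh$vertices[cluster, , drop = FALSE]
  ctr <- c(sum(xyz[, 1] * w), sum(xyz[, 2] * w), sum(xyz[, 3] * w)) / sum(w)
  d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  cluster[which.min(d2)]
}

# Full AFROC bookkeeping from first principles: for every threshold, every
# subject's marks; cumulative label detection; FPF/FPR from controls; AUC by
# trapezoid with (0,0) prepended and horizontal closure to FPF = 1.
oracle_afroc <- function(maps, labels_by_subject, control_ids, mesh, grid) {
  stat <- function(map) if (map$two_tailed) abs(map$values) else map$values
  n_thr <- length(grid)
  marks <- lapply(maps, function(mp) lapply(grid, function(tau) {
    comps <- oracle_components(mesh, stat(mp) >= tau)
    vapply(comps, function(cl) oracle_centroid(mesh, cl), 0L)
  }))
  lab_flat <- list(); owner <- character(0)
  for (sid in names(labels_by_subject))
    for (l in labels_by_subject[[sid]]) {
      lab_flat[[length(lab_flat) + 1L]] <- l
      owner <- c(owner, sid)
    }
  detected <- matrix(FALSE, length(lab_flat), n_thr)
  for (li in seq_along(lab_flat))
    for (k in seq_len(n_thr)) {
      hit <- any(marks[[owner[li]]][[k]] %in% lab_flat[[li]]$vertex_ids)
      detected[li, k] <- hit || (k > 1 && detected[li, k - 1])
    }
  tpf <- colMeans(detected)
  nclust <- t(vapply(control_ids,
                     function(sid) lengths(marks[[sid]]), numeric(n_thr)))
  fpf <- colMeans(nclust > 0)
  fpr <- colMeans(nclust)
  f <- c(0, fpf); t <- c(0, tpf)
  auc <- sum(diff(f) * (t[-length(t)] + t[-1]) / 2) +
    (1 - f[length(f)]) * t[length(t)]
  list(tpf = tpf, fpf = fpf, fpr = fpr, auc = auc, marks = marks)
}
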