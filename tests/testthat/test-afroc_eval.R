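test_that("threshold grids are data-adapted quantile sweeps", {
  m <- fixture_mesh(2)
  set.seed(21)
  maps <- lapply(1:6, function(i) smooth_map(m))
  grid <- threshold_grid(maps, 64)
  expect_true(all(diff(grid) < 0))
  pooled <- unlist(lapply(maps, `[[`, "values"))
  expect_true(all(grid %in% pooled))  # type-1 quantiles are observed values
  g1 <- threshold_grid(maps, 1)
  expect_length(g1, 1)
  const <- list(score_map(rep(2, m$nv), "IF"))
  expect_error(threshold_grid(const, 8), "constant")
  # two-tailed maps pool |z|
  zmaps <- lapply(maps, function(mp)
    score_map(mp$values, "GLM", two_tailed = TRUE))
  expect_true(min(threshold_grid(zmaps, 32)) >= 0)
})

test_that("mark extraction follows the threshold and tail conventions", {
  m <- fixture_mesh(2)
  v <- unname(which(lengths(m$adjacency) == 6)[1])
  patch1 <- c(v, m$adjacency[[v]])
  far <- which(m$hemisphere == "right")[40]
  patch2 <- c(far, m$adjacency[[far]])
  val <- numeric(m$nv)
  val[patch1] <- 5
  val[patch2] <- -5
  mp <- score_map(val, "GLM", two_tailed = TRUE)
  expect_length(extract_marks(mp, m, 10), 0)       # above the map range
  expect_length(extract_marks(mp, m, 4), 2)        # both tails marked
  one <- extract_marks(score_map(pmax(val, 0), "IF"), m, 4)
  expect_length(one, 1)
  expect_equal(one[[1]]$centroid, v)
  expect_true(one[[1]]$centroid %in% one[[1]]$cluster)
})

test_that("rating uses the strict centroid criterion and control-only FPs", {
  m <- fixture_mesh(2)
  v <- which(lengths(m$adjacency) == 6)[3]
  ring2 <- unique(c(v, unlist(m$adjacency[c(v, m$adjacency[[v]])])))
  lab <- surf_label(m, setdiff(ring2, v)[1:4], "lesion-wide")
  # cluster overlaps the label but its centroid (v) lies outside
  marks <- list(p1 = list(list(centroid = v, cluster = ring2)))
  r <- rate_marks(marks, list(p1 = list(lab)), character(0))
  expect_false(r$detected[["p1:1"]])
  # centroid inside counts even when most of the cluster is outside
  inside <- lab$vertex_ids[1]
  marks2 <- list(p1 = list(list(centroid = inside, cluster = ring2)))
  r2 <- rate_marks(marks2, list(p1 = list(lab)), character(0))
  expect_true(r2$detected[["p1:1"]])
  # patient clusters outside labels are not false positives
  r3 <- rate_marks(list(p1 = list(list(centroid = v, cluster = v)),
                        c1 = list()),
                   list(p1 = list(lab)), "c1")
  expect_equal(r3$fpr, 0)
  expect_equal(r3$fpf, 0)
})

test_that("oracle and empty maps bound the AFROC AUC", {
  m <- fixture_mesh(2)
  lab <- grow_disc_label(m, 25, radius_mm = 40, kind = "lesion-wide")
  ids <- sprintf("c%02d", 1:6)
  maps <- lapply(ids, function(i) score_map(numeric(m$nv), "IF", i))
  names(maps) <- ids
  oracle <- numeric(m$nv); oracle[lab$vertex_ids] <- 1
  maps[["p1"]] <- score_map(oracle, "IF", "p1")
  cv <- afroc_curve(maps, list(p1 = list(lab)), ids, m,
                    grid = c(0.9, 0.5, 0.1))
  expect_equal(cv$auc, 1)           # TPF 1 at FPF 0
  expect_equal(max(cv$points$FPF), 0)
  # all-zero maps yield no marks at any positive threshold
  maps[["p1"]] <- score_map(numeric(m$nv), "IF", "p1")
  cv0 <- afroc_curve(maps, list(p1 = list(lab)), ids, m,
                     grid = c(0.9, 0.5, 0.1))
  expect_equal(cv0$auc, 0)
})

test_that("TPF and FPF are monotone along the sweep and AUC converges", {
  m <- fixture_mesh(2)
  set.seed(31)
  ids <- sprintf("s%02d", 1:14)
  maps <- lapply(ids, function(i) smooth_map(m, i, two_tailed = TRUE))
  names(maps) <- ids
  labels <- list(s01 = list(grow_disc_label(m, 11, radius_mm = 35,
                                            kind = "hypothesis")),
                 s02 = list(grow_disc_label(m, 300, radius_mm = 30,
                                            kind = "hypothesis")))
  ctrl <- ids[3:14]
  cv <- afroc_curve(maps, labels, ctrl, m, threshold_grid(maps, 128))
  expect_true(all(diff(cv$points$TPF) >= 0))
  expect_true(all(diff(cv$points$FPF) >= 0))
  expect_true(all(cv$points$FPR >= 0))
  expect_gte(cv$auc, 0); expect_lte(cv$auc, 1)
  auc512 <- afroc_curve(maps, labels, ctrl, m, threshold_grid(maps, 512),
                        compute_fpr = FALSE)$auc
  auc4096 <- afroc_curve(maps, labels, ctrl, m, threshold_grid(maps, 4096),
                         compute_fpr = FALSE)$auc
  expect_lt(abs(auc512 - auc4096), 0.01)
})

test_that("guessing-style spike maps reproduce the closed-form AUC", {
  m <- fixture_mesh(3)
  lab <- grow_disc_label(m, which(lengths(m$adjacency) == 6)[50],
                         n_vertices = round(0.2 * m$nv), kind = "hypothesis")
  set.seed(9)
  aucs <- vapply(1:8, function(rep) {
    ids <- sprintf("s%03d", 1:120)
    maps <- lapply(ids, function(i) spike_map(m))
    names(maps) <- ids
    labels <- lapply(ids[1:60], function(i) list(lab))
    names(labels) <- ids[1:60]
    afroc_curve(maps, labels, ids[61:120], m, threshold_grid(maps, 256),
                compute_fpr = FALSE)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.2 / 1.2), 0.025)
})

test_that("per-lesion detection FPF covers the oracle and never-detected cases", {
  m <- fixture_mesh(2)
  lab <- grow_disc_label(m, 60, radius_mm = 40, kind = "lesion-wide")
  ids <- sprintf("c%02d", 1:5)
  maps <- lapply(ids, function(i) score_map(numeric(m$nv), "IF", i))
  names(maps) <- ids
  oracle <- numeric(m$nv); oracle[lab$vertex_ids] <- 1
  maps[["p1"]] <- score_map(oracle, "IF", "p1")
  r <- per_lesion_detection_fpf(maps, "p1", lab, ids, m, grid = c(0.9, 0.4))
  expect_true(r$detected)
  expect_equal(r$fpf_detection, 0)
  maps[["p1"]] <- score_map(numeric(m$nv), "IF", "p1")
  r0 <- per_lesion_detection_fpf(maps, "p1", lab, ids, m, grid = c(0.9, 0.4))
  expect_false(r0$detected)
  expect_equal(r0$fpf_detection, 1)
})
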