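test_that("template has icosphere vertex counts and mirror symmetry", {
  m2 <- fixture_mesh(2)
  m4 <- fixture_mesh(4)
  expect_equal(m2$nv_hemi, 10 * 4^2 + 2)
  expect_equal(m4$nv_hemi, 10 * 4^4 + 2)
  expect_equal(sum(m2$hemisphere == "left"), sum(m2$hemisphere == "right"))
  # right hemisphere is the left mirrored across x = 0, index i <-> i
  nvh <- m2$nv_hemi
  left <- m2$vertices[seq_len(nvh), ]
  right <- m2$vertices[seq_len(nvh) + nvh, ]
  expect_equal(right[, 1], -left[, 1], tolerance = 1e-12)
  expect_equal(right[, 2:3], left[, 2:3], tolerance = 1e-12)
  expect_error(build_symmetric_template(1), "coarse")
})

test_that("each hemisphere is a closed 2-manifold with consistent areas", {
  m <- fixture_mesh(2)
  f <- m$faces
  ek <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
              pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])))
  expect_true(all(table(ek) == 2))  # every edge shared by exactly 2 faces
  # independent face-area computation
  tri_area <- function(a, b, c) {
    u <- b - a; v <- c - a
    0.5 * sqrt(sum(crossprod(matrix(c(
      u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1])))))
  }
  tot <- sum(vapply(seq_len(nrow(f)), function(i)
    tri_area(m$vertices[f[i, 1], ], m$vertices[f[i, 2], ],
             m$vertices[f[i, 3], ]), 0))
  expect_equal(sum(m$vertex_area), tot, tolerance = 1e-6)
})

test_that("smoothing preserves constants, the global mean, and linearity", {
  m <- fixture_mesh(3)
  const <- rep(3.7, m$nv)
  expect_equal(smooth_field(m, const, 16), const, tolerance = 1e-9)
  set.seed(1)
  f <- rnorm(m$nv); g <- rnorm(m$nv)
  sf <- smooth_field(m, f, 12)
  expect_equal(mean(sf), mean(f), tolerance = 1e-9)
  # area-weighted mass conserved closely on the quasi-uniform mesh
  expect_equal(sum(sf * m$vertex_area), sum(f * m$vertex_area),
               tolerance = 2e-2)
  lin <- smooth_field(m, 2 * f + 3 * g, 12)
  expect_equal(lin, 2 * sf + 3 * smooth_field(m, g, 12), tolerance = 1e-9)
  expect_error(smooth_field(m, c(f[-1], NA), 8), "finite")
  expect_error(smooth_field(m, f, -1), "positive")
})

test_that("point-source response recovers the requested geodesic FWHM", {
  m <- fixture_mesh(4)
  v0 <- which(lengths(m$adjacency) == 6)[200]
  ps <- numeric(m$nv); ps[v0] <- 1
  d <- geodesic_from(m, v0)
  fitted_fwhm <- function(fwhm) {
    r <- smooth_field(m, ps, fwhm)
    idx <- which(is.finite(d) & r > max(r) * 1e-4)
    fit <- lm(log(r[idx]) ~ I(d[idx]^2), weights = r[idx])
    2 * sqrt(2 * log(2)) * sqrt(-1 / (2 * coef(fit)[[2]]))
  }
  expect_gt(fitted_fwhm(8), 6.8)
  expect_lt(fitted_fwhm(8), 9.2)
  expect_lt(abs(fitted_fwhm(32) - 32) / 32, 0.15)
})

test_that("connected components partition the mask and respect hemispheres", {
  m <- fixture_mesh(2)
  expect_length(connected_components(m, rep(FALSE, m$nv)), 0)
  # all-true mask: one component per hemisphere (no shared edges)
  expect_length(connected_components(m, rep(TRUE, m$nv)), 2)
  # two disjoint patches
  p1 <- c(5, m$adjacency[[5]])
  far <- which.max(geodesic_from(m, 5))
  p2 <- c(far, m$adjacency[[far]])
  mask <- rep(FALSE, m$nv); mask[c(p1, p2)] <- TRUE
  cc <- connected_components(m, mask)
  expect_length(cc, 2)
  # partition property on random masks, against the igraph oracle
  set.seed(7)
  for (i in 1:5) {
    mask <- runif(m$nv) < 0.3
    cc <- connected_components(m, mask)
    expect_equal(sort(unlist(cc)), which(mask))
    expect_equal(lapply(cc, sort), lapply(oracle_components(m, mask), sort))
  }
})

test_that("cluster centroids are on-surface, deterministic and order-invariant", {
  m <- fixture_mesh(2)
  expect_equal(cluster_centroid(m, 17L), 17L)
  v <- unname(which(lengths(m$adjacency) == 6)[1])
  ring <- c(v, m$adjacency[[v]])
  expect_equal(cluster_centroid(m, ring), v)  # symmetric 1-ring
  # elongated cluster: brute force over members
  d <- geodesic_from(m, v)
  clus <- order(d)[1:12]
  w <- m$vertex_area[clus]
  ctr <- colSums(m$vertices[clus, ] * w) / sum(w)
  d2 <- rowSums(sweep(m$vertices[clus, ], 2, ctr)^2)
  expect_equal(cluster_centroid(m, clus), sort(clus)[which.min(d2[order(clus)])])
  expect_equal(cluster_centroid(m, rev(clus)), cluster_centroid(m, clus))
  expect_error(cluster_centroid(m, integer(0)), "non-empty")
})

test_that("label dilation grows monotonically and k = 0 is the identity", {
  m <- fixture_mesh(2)
  v <- which(lengths(m$adjacency) == 6)[1]
  lab <- surf_label(m, v, "lesion-strict")
  expect_equal(dilate_label(m, lab, 0)$vertex_ids, lab$vertex_ids)
  d1 <- dilate_label(m, lab, 1)
  expect_length(d1$vertex_ids, 7)  # degree-6 singleton gains its 1-ring
  phis <- vapply(0:4, function(k) dilate_label(m, lab, k)$phi, 0)
  expect_true(all(diff(phis) >= 0))
  expect_true(all(lab$vertex_ids %in% d1$vertex_ids))
})

test_that("relative label size is an area ratio and additive", {
  m <- fixture_mesh(2)
  expect_equal(relative_label_size(m, seq_len(m$nv)), 1)
  expect_equal(relative_label_size(m, integer(0)), 0)
  expect_equal(relative_label_size(m, which(m$hemisphere == "left")), 0.5,
               tolerance = 1e-12)
  set.seed(3)
  a <- sample.int(m$nv, 40)
  b <- setdiff(sample.int(m$nv, 60), a)
  expect_equal(relative_label_size(m, c(a, b)),
               relative_label_size(m, a) + relative_label_size(m, b))
})

test_that("parcellation is contiguous, exhaustive and reproducible", {
  m <- fixture_mesh(3)
  p <- build_parcels(m, 8, seed = 5)
  expect_equal(sort(unique(p)), 1:16)
  expect_length(p, m$nv)
  for (k in c(1, 5, 12)) {
    mask <- p == k
    expect_length(connected_components(m, mask), 1)
  }
  expect_identical(p, build_parcels(m, 8, seed = 5))
  p1 <- build_parcels(m, 1, seed = 2)
  expect_equal(sort(unique(p1[m$hemisphere == "left"])), 1)
})

test_that("labels and meshes round-trip through their text formats", {
  m <- fixture_mesh(2)
  lab <- grow_disc_label(m, 40, radius_mm = 30, kind = "hypothesis")
  path <- tempfile(fileext = ".label")
  write_surface_label(lab, path)
  lab2 <- read_surface_label(m, path)
  expect_equal(lab2$vertex_ids, lab$vertex_ids)
  expect_equal(lab2$kind, lab$kind)
  expect_equal(lab2$phi, lab$phi)
  ply <- tempfile(fileext = ".ply")
  write_ply(m, ply)
  head <- readLines(ply, n = 3)
  expect_equal(head[1], "ply")
  expect_match(head[3], as.character(m$nv))
})
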