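# Template surface construction and geometric primitives: icosphere
# hemispheres, Laplacian smoothing calibrated to a geodesic FWHM, connected
# components, centroids, label morphology and relative label size (phi).

# ---- icosphere --------------------------------------------------------------

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(vertices, faces) {
  nv <- nrow(vertices)
  key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  midpoints <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vertices
  midpoint <- function(a, b) {
    k <- key(a, b)
    id <- midpoints[[k]]
    if (!is.null(id)) return(id)
    m <- (verts[a, ] + verts[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    id <- nrow(verts)
    midpoints[[k]] <- id
    id
  }
  newf <- matrix(0L, nrow(faces) * 4L, 3L)
  for (i in seq_len(nrow(faces))) {
    a <- faces[i, 1]; b <- faces[i, 2]; c <- faces[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[(i - 1L) * 4L + 1L, ] <- c(a, ab, ca)
    newf[(i - 1L) * 4L + 2L, ] <- c(b, bc, ab)
    newf[(i - 1L) * 4L + 3L, ] <- c(c, ca, bc)
    newf[(i - 1L) * 4L + 4L, ] <- c(ab, bc, ca)
  }
  list(vertices = verts, faces = newf)
}

icosphere <- function(level) {
  m <- icosahedron()
  for (i in seq_len(level)) m <- subdivide_once(m$vertices, m$faces)
  m
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# ---- template construction --------------------------------------------------

#' Build a symmetric two-hemisphere template mesh
#'
#' Constructs two mirrored icosphere "hemispheres" (each a closed sphere mesh,
#' so every edge is shared by exactly two faces) of the given subdivision
#' level and radius. Left and right hemispheres have identical topology and
#' index correspondence `i <-> i`, emulating a symmetric cortical template on
#' which per-vertex maps, labels and asymmetry features live. The default
#' radius of 100 mm gives a total surface area of the same order as a human
#' cortex, so smoothing kernels and lesion radii stated in millimetres keep
#' their physical meaning.
#'
#' A smoothing calibration (variance gained per Laplacian iteration, fitted
#' from a point-source response) is computed once and stored with the mesh;
#' [smooth_field()] uses it to hit a requested geodesic FWHM.
#'
#' @param subdivision_level integer >= 2; vertex count per hemisphere is
#'   `10 * 4^level + 2`.
#' @param radius_mm sphere radius in millimetres.
#' @return an object of class `surf_mesh` with fields `vertices` (n x 3, mm),
#'   `faces`, `hemisphere` ("left"/"right" per vertex), `vertex_area` (mm^2,
#'   one third of incident triangle areas), `adjacency` (neighbor index
#'   lists) and `edges`.
#' @export
build_symmetric_template <- function(subdivision_level = 4L, radius_mm = 100) {
  if (subdivision_level < 2)
    stopf("subdivision_level must be >= 2 (mesh too coarse for clustering)")
  if (radius_mm <= 0) stopf("radius_mm must be positive")
  ico <- icosphere(subdivision_level)
  nvh <- nrow(ico$vertices)
  offset <- radius_mm * 1.1
  left <- ico$vertices * radius_mm
  left[, 1] <- left[, 1] - offset
  right <- ico$vertices * radius_mm
  right[, 1] <- -right[, 1] + offset  # mirror across x = 0
  vertices <- rbind(left, right)
  faces <- rbind(ico$faces, ico$faces[, c(1, 3, 2)] + nvh)
  nv <- 2L * nvh

  fa <- face_areas(vertices, faces)
  vertex_area <- as.numeric(rowsum(rep(fa / 3, 3L), as.integer(faces),
                                   reorder = TRUE))

  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  adjacency <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  adjacency <- lapply(adjacency, function(x) sort(unique(as.integer(x))))
  deg <- lengths(adjacency)

  laplacian <- Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2], seq_len(nv)),
    j = c(e[, 2], e[, 1], seq_len(nv)),
    x = c(rep(1, 2L * nrow(e)), -deg),
    dims = c(nv, nv))
  tau <- 1 / (2 * max(deg))

  mesh <- structure(list(
    vertices = vertices, faces = faces,
    hemisphere = rep(c("left", "right"), each = nvh),
    vertex_area = vertex_area, adjacency = adjacency, edges = e,
    laplacian = laplacian, tau = tau,
    nv = nv, nv_hemi = nvh, level = subdivision_level,
    radius = radius_mm,
    centers = rbind(c(-offset, 0, 0), c(offset, 0, 0))),
    class = "surf_mesh")
  mesh$sigma2_per_step <- calibrate_smoothing(mesh)
  mesh
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf(paste0("surf_mesh: %d vertices (%d per hemisphere), %d faces,",
                     " radius %.0f mm, area %.3g mm^2\n"),
              x$nv, x$nv_hemi, nrow(x$faces), x$radius, sum(x$vertex_area)))
  invisible(x)
}

#' Geodesic distance from one vertex to all vertices of its hemisphere
#'
#' Exact great-circle distance on the template sphere; vertices of the other
#' hemisphere get `Inf`.
#'
#' @param mesh a `surf_mesh`.
#' @param v vertex index.
#' @return numeric vector of length `mesh$nv` (mm).
#' @export
geodesic_from <- function(mesh, v) {
  hemi <- mesh$hemisphere[v]
  ctr <- mesh$centers[if (hemi == "left") 1 else 2, ]
  d <- rep(Inf, mesh$nv)
  idx <- which(mesh$hemisphere == hemi)
  u <- sweep(mesh$vertices[idx, , drop = FALSE], 2, ctr) / mesh$radius
  w <- (mesh$vertices[v, ] - ctr) / mesh$radius
  cosang <- pmin(1, pmax(-1, as.numeric(u %*% w)))
  d[idx] <- mesh$radius * acos(cosang)
  d
}

# Fit the variance (sigma^2, in mm^2 of geodesic distance) gained per
# explicit-Euler Laplacian step, from the spread of a point-source response.
calibrate_smoothing <- function(mesh, n_steps = 40L) {
  deg <- lengths(mesh$adjacency)
  v0 <- which(deg == max(deg))[1]
  d2 <- geodesic_from(mesh, v0)^2
  d2 <- ifelse(is.finite(d2), d2, 0)
  f <- numeric(mesh$nv); f[v0] <- 1
  spread <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    f <- f + mesh$tau * as.numeric(mesh$laplacian %*% f)
    spread[i] <- sum(f * d2) / sum(f)
  }
  lo <- max(2L, n_steps %/% 4L)
  fit <- lm(spread[lo:n_steps] ~ seq(lo, n_steps))
  as.numeric(coef(fit)[2]) / 2  # E[d^2] = 2 sigma^2 for an isotropic kernel
}

# ---- smoothing --------------------------------------------------------------

#' Smooth a per-vertex field with an approximate geodesic Gaussian kernel
#'
#' Iterative neighbor averaging (explicit heat-kernel steps with the
#' combinatorial graph Laplacian), with the iteration count chosen from the
#' template's stored calibration so that a point-source response has the
#' requested full width at half maximum. The operator is linear, leaves
#' constant fields untouched, conserves the global vertex mean exactly and
#' the area-weighted integral to high accuracy on the quasi-uniform
#' icosphere. FWHM values well below the mesh edge length cannot be realised
#' exactly; the kernel then degenerates towards the identity.
#'
#' @param mesh a `surf_mesh`.
#' @param field numeric vector (length `mesh$nv`) or matrix (rows = vertices);
#'   all values must be finite.
#' @param fwhm_mm requested geodesic FWHM in millimetres (> 0).
#' @return smoothed field, same shape as the input.
#' @export
smooth_field <- function(mesh, field, fwhm_mm) {
  stopifnot(inherits(mesh, "surf_mesh"))
  if (!all(is.finite(field))) stopf("field contains non-finite values")
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || fwhm_mm <= 0)
    stopf("fwhm_mm must be a positive scalar")
  vec <- is.null(dim(field))
  f <- if (vec) matrix(field, ncol = 1) else field
  if (nrow(f) != mesh$nv) stopf("field must have one value per vertex")
  sigma2 <- (fwhm_mm / (2 * sqrt(2 * log(2))))^2
  nu <- sigma2 / mesh$sigma2_per_step
  n_full <- floor(nu)
  rem <- nu - n_full
  L <- mesh$laplacian
  tau <- mesh$tau
  for (i in seq_len(n_full)) f <- f + tau * as.matrix(L %*% f)
  if (rem > 0) f <- f + (tau * rem) * as.matrix(L %*% f)
  if (vec) as.numeric(f) else f
}

# ---- clustering -------------------------------------------------------------

#' Connected components of a suprathreshold vertex mask
#'
#' Partitions masked vertices into maximal edge-connected sets. The two
#' hemispheres share no edges and therefore never merge.
#'
#' @param mesh a `surf_mesh`.
#' @param mask logical vector, one value per vertex.
#' @return list of integer vertex-index vectors (possibly empty list),
#'   ordered by their smallest member index.
#' @export
connected_components <- function(mesh, mask) {
  stopifnot(length(mask) == mesh$nv)
  mask <- as.logical(mask)
  if (!any(mask)) return(list())
  lab <- cc_masked(mesh$nv, mesh$edges[, 1], mesh$edges[, 2], mask)
  idx <- which(lab > 0L)
  unname(split(idx, lab[idx]))
}

#' Area-weighted centroid vertex of a cluster
#'
#' Returns the cluster member nearest (Euclidean) to the area-weighted mean
#' coordinate of the cluster, so the centroid always lies on the surface and
#' "centroid inside label" is well defined. Ties break to the lowest vertex
#' index.
#'
#' @param mesh a `surf_mesh`.
#' @param cluster non-empty integer vector of vertex indices.
#' @return a single vertex index.
#' @export
cluster_centroid <- function(mesh, cluster) {
  cluster <- as.integer(cluster)
  if (length(cluster) == 0) stopf("cluster must be non-empty")
  cluster <- sort(cluster)
  w <- mesh$vertex_area[cluster]
  ctr <- colSums(mesh$vertices[cluster, , drop = FALSE] * w) / sum(w)
  d2 <- rowSums(sweep(mesh$vertices[cluster, , drop = FALSE], 2, ctr)^2)
  cluster[which.min(d2)]
}

# ---- labels -----------------------------------------------------------------

#' Create a surface label
#'
#' @param mesh a `surf_mesh`.
#' @param vertex_ids integer vertex indices.
#' @param kind one of "lesion-strict", "lesion-wide", "hypothesis".
#' @return object of class `surf_label` with fields `vertex_ids`, `kind`,
#'   `phi` (relative area).
#' @export
surf_label <- function(mesh, vertex_ids, kind = c("lesion-strict",
                                                  "lesion-wide",
                                                  "hypothesis")) {
  kind <- match.arg(kind)
  vertex_ids <- sort(unique(as.integer(vertex_ids)))
  if (any(vertex_ids < 1 | vertex_ids > mesh$nv))
    stopf("vertex_ids out of range")
  structure(list(vertex_ids = vertex_ids, kind = kind,
                 phi = relative_label_size(mesh, vertex_ids)),
            class = "surf_label")
}

#' @export
print.surf_label <- function(x, ...) {
  cat(sprintf("surf_label (%s): %d vertices, phi = %.4g\n",
              x$kind, length(x$vertex_ids), x$phi))
  invisible(x)
}

#' Relative label size phi
#'
#' Ratio of the label's summed vertex area to the total surface area of both
#' hemispheres; the size parameter of the guessing-null closed form.
#'
#' @param mesh a `surf_mesh`.
#' @param label a `surf_label` or an integer vector of vertex indices.
#' @return a number in `[0, 1]`.
#' @export
relative_label_size <- function(mesh, label) {
  ids <- if (inherits(label, "surf_label")) label$vertex_ids
         else as.integer(label)
  if (length(ids) == 0) return(0)
  if (any(ids < 1 | ids > mesh$nv)) stopf("label vertex indices out of range")
  sum(mesh$vertex_area[ids]) / sum(mesh$vertex_area)
}

#' Morphological dilation of a label
#'
#' `k` rounds of adding all mesh neighbors of current members; used to turn
#' strict lesion labels into the wide evaluation version (the 4-vertex
#' dilation convention).
#'
#' @param mesh a `surf_mesh`.
#' @param label a `surf_label`.
#' @param k number of dilation rounds (>= 0).
#' @return a `surf_label` of the same kind unless `kind` is given.
#' @param kind optional new kind for the returned label.
#' @export
dilate_label <- function(mesh, label, k = 4L, kind = NULL) {
  stopifnot(inherits(label, "surf_label"), k >= 0)
  ids <- label$vertex_ids
  for (i in seq_len(k)) {
    ids <- sort(unique(c(ids, unlist(mesh$adjacency[ids], use.names = FALSE))))
  }
  surf_label(mesh, ids, kind %||% label$kind)
}

#' Grow a geodesic disc label
#'
#' Grows a label around a seed vertex out to `radius_mm`, or (if
#' `phi_target` is given) to the smallest geodesic disc whose relative area
#' reaches the target; used for implanted lesions and for constructing label
#' sets with prescribed phi statistics.
#'
#' @param mesh a `surf_mesh`.
#' @param seed_vertex vertex index at the disc center.
#' @param radius_mm geodesic radius (mm), ignored when `phi_target` or
#'   `n_vertices` is given.
#' @param phi_target optional relative area in (0, 1].
#' @param n_vertices optional exact member count (the disc is the
#'   `n_vertices` nearest vertices); useful when the vertex fraction rather
#'   than the area fraction must hit a target, as in the vertex-uniform
#'   guessing null.
#' @param kind label kind, see [surf_label()].
#' @return a `surf_label`.
#' @export
grow_disc_label <- function(mesh, seed_vertex, radius_mm = NULL,
                            phi_target = NULL, n_vertices = NULL,
                            kind = "lesion-strict") {
  d <- geodesic_from(mesh, seed_vertex)
  if (!is.null(n_vertices)) {
    stopifnot(n_vertices >= 1, n_vertices <= sum(is.finite(d)))
    ids <- order(d)[seq_len(n_vertices)]
  } else if (!is.null(phi_target)) {
    stopifnot(phi_target > 0, phi_target <= 1)
    ord <- order(d)
    cum <- cumsum(mesh$vertex_area[ord]) / sum(mesh$vertex_area)
    n <- which(cum >= phi_target)[1]
    if (is.na(n)) stopf("phi_target exceeds one hemisphere")
    ids <- ord[seq_len(n)]
  } else {
    stopifnot(!is.null(radius_mm), radius_mm > 0)
    if (radius_mm >= pi * mesh$radius)
      stopf("radius exceeds hemisphere size")
    ids <- which(d <= radius_mm)
  }
  surf_label(mesh, ids, kind)
}

# ---- parcellation -----------------------------------------------------------

#' Synthetic contiguous parcellation of each hemisphere
#'
#' Multi-source breadth-first flood fill from randomly chosen seed vertices:
#' parcels are contiguous, non-overlapping and exhaustive per hemisphere, an
#' analog of lobar atlas labels for hypothesis-based evaluation.
#'
#' @param mesh a `surf_mesh`.
#' @param n_parcels_per_hemisphere integer in `[1, 50]`.
#' @param seed integer seed for reproducible seeds of the flood fill.
#' @return integer vector of parcel ids per vertex (left hemisphere gets
#'   parcels `1..n`, right `n+1..2n`).
#' @export
build_parcels <- function(mesh, n_parcels_per_hemisphere = 8L, seed = 1L) {
  n <- as.integer(n_parcels_per_hemisphere)
  if (n < 1 || n > 50) stopf("n_parcels_per_hemisphere must be in [1, 50]")
  nvh <- mesh$nv_hemi
  parcel <- integer(mesh$nv)
  with_seed(seed, {
    for (h in 0:1) {
      verts <- seq_len(nvh) + h * nvh
      seeds <- sample(verts, n)
      parcel[seeds] <- seq_len(n) + h * n
      frontier <- as.list(seeds)
      repeat {
        grew <- FALSE
        for (p in seq_len(n)) {
          fr <- frontier[[p]]
          if (length(fr) == 0) next
          nb <- unique(unlist(mesh$adjacency[fr], use.names = FALSE))
          nb <- nb[parcel[nb] == 0L]
          if (length(nb) > 0) {
            parcel[nb] <- p + h * n
            grew <- TRUE
          }
          frontier[[p]] <- nb
        }
        if (!grew) break
      }
    }
  })
  parcel
}

# ---- input/output -----------------------------------------------------------

#' Write the template mesh as ASCII PLY
#' @param mesh a `surf_mesh`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", mesh$nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh$vertices, trim = TRUE), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(cbind(3L, mesh$faces - 1L), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a surface label as a plain-text vertex-index file
#'
#' One vertex index per line, preceded by comment lines recording the label
#' kind and phi.
#'
#' @param label a `surf_label`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_surface_label <- function(label, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind %s", label$kind),
               sprintf("# phi %.10g", label$phi),
               as.character(label$vertex_ids)), con)
  invisible(path)
}

#' Read a surface label written by [write_surface_label()]
#' @param mesh a `surf_mesh` (phi is recomputed against it).
#' @param path input file path.
#' @return a `surf_label`.
#' @export
read_surface_label <- function(mesh, path) {
  lines <- readLines(path)
  kind <- sub("^# kind ", "", lines[grepl("^# kind ", lines)][1])
  ids <- as.integer(lines[!grepl("^#", lines)])
  surf_label(mesh, ids, kind)
}
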