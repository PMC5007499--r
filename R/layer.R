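#' Parameters for Purkinje-layer extraction and density estimation
#'
#' The layer domain is found by sorting detected objects into a grid of
#' `grid_spacing_vox` cubes and keeping the largest 6-connected set of
#' filled cubes. The layer manifold is the zero level set of the smoothed
#' distance-to-cells field, evaluated on a coarse grid with spacing
#' `dist_grid_spacing_vox` and offset by `zero_level_vox` (default 44
#' voxels). Local density counts cells in a `density_radius_um`
#' neighbourhood (default 100 um).
#'
#' @param grid_spacing_vox Cube edge for the layer-domain grid (voxels).
#' @param grid_connectivity Cube adjacency for the layer-domain components,
#'   6 (faces) or 26 (faces, edges, corners). Default 26: on sparsely
#'   populated grids the folded cell sheet steps diagonally between cubes,
#'   which face-adjacency would disconnect.
#' @param dist_grid_spacing_vox Coarse distance-grid spacing (voxels).
#' @param zero_level_vox Offset of the zero level set (voxels).
#' @param smoothing_sigma_nodes Gaussian smoothing of the coarse distance
#'   field, in grid-node units.
#' @param density_radius_um Neighbourhood radius for local density (um).
#' @return An object of class `layer_params`.
#' @export
layer_params <- function(grid_spacing_vox = 50, grid_connectivity = 26,
                         dist_grid_spacing_vox = 10,
                         zero_level_vox = 44, smoothing_sigma_nodes = 2,
                         density_radius_um = 100) {
  vals <- c(grid_spacing_vox, dist_grid_spacing_vox, zero_level_vox,
            smoothing_sigma_nodes, density_radius_um)
  if (any(vals <= 0)) stop("all layer parameters must be positive")
  if (!grid_connectivity %in% c(6, 26))
    stop("`grid_connectivity` must be 6 or 26")
  structure(list(grid_spacing_vox = as.integer(grid_spacing_vox),
                 grid_connectivity = as.integer(grid_connectivity),
                 dist_grid_spacing_vox = as.integer(dist_grid_spacing_vox),
                 zero_level_vox = zero_level_vox,
                 smoothing_sigma_nodes = smoothing_sigma_nodes,
                 density_radius_um = density_radius_um),
            class = "layer_params")
}

as_centroid_matrix <- function(cells) {
  if (is.data.frame(cells)) cells <- as.matrix(cells[, c("z", "y", "x")])
  cells <- as.matrix(cells)
  if (ncol(cells) != 3L) stop("centroids must be an N x 3 (z, y, x) matrix")
  storage.mode(cells) <- "double"
  colnames(cells) <- c("z", "y", "x")
  cells
}

#' Select the Purkinje-layer object population by grid connectivity
#'
#' Mis-segmentations away from the cell layer are sparse, while the layer
#' itself fills a connected band of space. The volume is partitioned into
#' cubes of `grid_spacing_vox` voxels; a cube is filled iff it contains at
#' least one centroid; the centroids lying in cubes of the largest
#' connected component of filled cubes (adjacency per
#' `p$grid_connectivity`) are kept. Ties between equally large components
#' resolve to the one containing the smallest linear (column-major
#' (z, y, x)) cube index, so the output is deterministic.
#'
#' @param cells N x 3 matrix (or data.frame with z, y, x columns) of
#'   centroids in voxel coordinates.
#' @param p A [layer_params()] object.
#' @param volume_shape Integer triple, shape of the parent volume.
#' @return The subset of rows of `cells` in the largest component, with the
#'   selected row indices as attribute `selected`.
#' @export
select_layer_population <- function(cells, p, volume_shape) {
  cells <- as_centroid_matrix(cells)
  if (nrow(cells) == 0L) {
    attr(cells, "selected") <- integer()
    return(cells)
  }
  h <- p$grid_spacing_vox
  gd <- pmax(as.integer(ceiling(volume_shape / h)), 1L)
  ci <- pmin(pmax(floor((cells - 1) / h), 0), matrix(gd - 1L, nrow(cells), 3,
                                                     byrow = TRUE))
  lin <- ci[, 1] + ci[, 2] * gd[1] + ci[, 3] * gd[1] * gd[2] + 1
  filled <- logical(prod(gd))
  filled[lin] <- TRUE
  labels <- .cpp_label3d(filled, gd, p$grid_connectivity)
  n_lab <- attr(labels, "n_labels")
  sizes <- tabulate(labels[labels > 0L], nbins = n_lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component containing the smallest linear cube index
    first_idx <- vapply(best, function(b) min(which(labels == b)), numeric(1))
    best <- best[which.min(first_idx)]
  }
  keep <- which(labels[lin] == best)
  out <- cells[keep, , drop = FALSE]
  attr(out, "selected") <- keep
  out
}

# ---------------------------------------------------------------------------
# Marching tetrahedra on a rectilinear node grid. Each grid cube is split
# into the six Kuhn tetrahedra sharing the main diagonal; the phi = 0
# isosurface is linearly interpolated along sign-crossing edges. Vertices
# are not merged across triangles (areas and per-vertex sampling are
# unaffected).
march_tets <- function(phi, node_coords) {
  g <- dim(phi)
  if (any(g < 2L)) stop("coarse grid too small for surface extraction")
  pv <- as.vector(phi)
  pv[pv == 0] <- -1e-12  # avoid exactly-zero corners
  # corner linear offsets, bit order (z, y, x): corner k has bits (kx,ky,kz)
  corner_off <- function(bz, by, bx) bz + by * g[1] + bx * g[1] * g[2]
  # corners numbered 0..7 with bit0 = z, bit1 = y, bit2 = x
  offs <- vapply(0:7, function(k)
    corner_off(bitwAnd(k, 1L), bitwAnd(bitwShiftR(k, 1L), 1L),
               bitwAnd(bitwShiftR(k, 2L), 1L)), numeric(1))
  tets <- rbind(c(0, 1, 3, 7), c(0, 2, 3, 7), c(0, 1, 5, 7),
                c(0, 4, 5, 7), c(0, 2, 6, 7), c(0, 4, 6, 7)) + 1L
  # base linear index of corner 0 for every cube
  bz <- seq_len(g[1] - 1L); by <- seq_len(g[2] - 1L); bx <- seq_len(g[3] - 1L)
  base <- as.vector(outer(outer(bz, (by - 1L) * g[1], "+"),
                          (bx - 1L) * g[1] * g[2], "+"))
  tri_list <- vector("list", 64L)
  nt <- 0L
  interp <- function(i1, i2) {
    p1 <- pv[i1]; p2 <- pv[i2]
    t <- p1 / (p1 - p2)
    node_coords[i1, , drop = FALSE] +
      t * (node_coords[i2, , drop = FALSE] - node_coords[i1, , drop = FALSE])
  }
  for (tt in seq_len(6L)) {
    I <- cbind(base + offs[tets[tt, 1]], base + offs[tets[tt, 2]],
               base + offs[tets[tt, 3]], base + offs[tets[tt, 4]])
    P <- matrix(pv[I], ncol = 4L)
    neg <- P < 0
    ns <- rowSums(neg)
    # one corner on its own side: single triangle from its three edges
    for (c0 in 1:4) {
      rest <- setdiff(1:4, c0)
      rows <- which((ns == 1L & neg[, c0]) | (ns == 3L & !neg[, c0]))
      if (!length(rows)) next
      a <- interp(I[rows, c0], I[rows, rest[1]])
      b <- interp(I[rows, c0], I[rows, rest[2]])
      cc <- interp(I[rows, c0], I[rows, rest[3]])
      nt <- nt + 1L
      tri_list[[nt]] <- cbind(a, b, cc)
    }
    # two against two: quad split into two triangles
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (pp in seq_len(nrow(pairs))) {
      ab <- pairs[pp, ]; cd <- setdiff(1:4, ab)
      rows <- which(ns == 2L & neg[, ab[1]] & neg[, ab[2]])
      if (!length(rows)) next
      e1 <- interp(I[rows, ab[1]], I[rows, cd[1]])
      e2 <- interp(I[rows, ab[1]], I[rows, cd[2]])
      e3 <- interp(I[rows, ab[2]], I[rows, cd[2]])
      e4 <- interp(I[rows, ab[2]], I[rows, cd[1]])
      nt <- nt + 2L
      tri_list[[nt - 1L]] <- cbind(e1, e2, e3)
      tri_list[[nt]] <- cbind(e1, e3, e4)
    }
  }
  tri <- do.call(rbind, tri_list[seq_len(nt)])
  if (is.null(tri) || nrow(tri) == 0L)
    stop("no zero crossing of the level set inside the coarse grid")
  # tri: (ntri) x 9 = three (z, y, x) points per row
  v <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
             tri[, 7:9, drop = FALSE])
  n <- nrow(tri)
  f <- cbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n)
  list(vertices = v, faces = f)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Construct a layer-surface object
#'
#' Normally produced by [extract_layer_surface()]; the constructor is
#' exported so synthetic surfaces can be built directly (e.g. for density
#' estimation on known geometry).
#'
#' @param vertices_um V x 3 matrix of vertex positions (z, y, x) in um.
#' @param faces F x 3 integer matrix of vertex indices.
#' @param voxel_len_um Voxel length of the parent volume (um).
#' @param volume_shape Integer triple, shape of the parent volume.
#' @param sample_points_um V x 3 matrix of per-vertex density sampling
#'   points (defaults to the vertices themselves).
#' @return An object of class `layer_surface`.
#' @export
layer_surface <- function(vertices_um, faces, voxel_len_um, volume_shape,
                          sample_points_um = vertices_um) {
  areas <- triangle_areas(vertices_um, faces)
  structure(list(vertices_um = vertices_um, faces = faces,
                 face_areas_um2 = areas,
                 area_mm2 = sum(areas) / 1e6,
                 voxel_len_um = voxel_len_um,
                 volume_shape = as.integer(volume_shape),
                 sample_points_um = sample_points_um,
                 density_mm2 = NULL, summary = NULL),
            class = "layer_surface")
}

#' @export
print.layer_surface <- function(x, ...) {
  cat(sprintf("<layer_surface> %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices_um), nrow(x$faces), x$area_mm2))
  if (!is.null(x$summary)) {
    s <- x$summary
    cat(sprintf("  n_cells %d | mean local density %.1f /mm^2 | global %.1f /mm^2 | %.1f /mm^3\n",
                s$n_cells, s$mean_density_per_mm2, s$global_density_per_mm2,
                s$volumetric_density_per_mm3))
  }
  invisible(x)
}

#' Extract the Purkinje-layer manifold from cell positions
#'
#' Distances to the nearest cell centroid are evaluated on a coarse grid
#' (spacing `dist_grid_spacing_vox`), smoothed with a Gaussian of
#' `smoothing_sigma_nodes` grid nodes, and the zero level set of
#' (smoothed distance - `zero_level_vox`) is triangulated by marching
#' tetrahedra. The resulting closed offset surface encloses the cell sheet
#' at a distance of `zero_level_vox` voxels on both sides (so its area is
#' about twice the mid-layer area); it is clipped at the coarse-grid
#' boundary. Each vertex also carries a sampling point: its projection back
#' onto the cell sheet along the gradient of the smoothed distance field,
#' used by [local_density()].
#'
#' @param cells N x 3 centroid matrix (voxel coordinates), N >= 1 (a single
#'   centroid yields the offset sphere around it).
#' @param p A [layer_params()] object.
#' @param volume_shape Integer triple, shape of the parent volume (voxels).
#' @param voxel_len_um Voxel length in um.
#' @return A [layer_surface()] with vertices in um.
#' @export
extract_layer_surface <- function(cells, p, volume_shape, voxel_len_um) {
  cells <- as_centroid_matrix(cells)
  if (nrow(cells) < 1L)
    stop("cannot extract a layer surface from an empty centroid set")
  h <- p$dist_grid_spacing_vox
  node_ax <- lapply(1:3, function(a) seq(1, volume_shape[a], by = h))
  g <- vapply(node_ax, length, integer(1))
  if (any(g < 2L)) stop("volume too small for the coarse distance grid")
  nodes <- as.matrix(expand.grid(z = node_ax[[1]], y = node_ax[[2]],
                                 x = node_ax[[3]], KEEP.OUT.ATTRS = FALSE))
  dist_vox <- nearest_distances(nodes, cells)
  dim(dist_vox) <- g
  sm <- gauss_smooth3d(dist_vox, p$smoothing_sigma_nodes)
  phi <- sm - p$zero_level_vox
  if (all(phi > 0) || all(phi < 0))
    stop("no zero crossing of the level set inside the coarse grid")
  node_coords <- nodes  # voxel units
  mesh <- march_tets(phi, node_coords)
  verts_vox <- mesh$vertices
  # gradient of the smoothed distance field at the vertices -> projection
  # of each vertex back onto the cell sheet
  grad <- array(0, c(g, 3))
  for (a in 1:3) {
    idx_p <- pmin(slice.index(sm, a) + 1L, g[a])
    idx_m <- pmax(slice.index(sm, a) - 1L, 1L)
    span <- (idx_p - idx_m) * h
    others <- lapply(1:3, function(b) slice.index(sm, b))
    others[[a]] <- idx_p
    vp <- sm[cbind(as.vector(others[[1]]), as.vector(others[[2]]),
                   as.vector(others[[3]]))]
    others[[a]] <- idx_m
    vm <- sm[cbind(as.vector(others[[1]]), as.vector(others[[2]]),
                   as.vector(others[[3]]))]
    grad[, , , a] <- array((vp - vm) / as.vector(span), g)
  }
  gv <- interp_trilinear(grad, node_ax, verts_vox)
  gn <- sqrt(rowSums(gv^2))
  gn[gn == 0] <- 1
  samples_vox <- verts_vox - p$zero_level_vox * gv / gn
  surf <- layer_surface((verts_vox - 1) * voxel_len_um, mesh$faces,
                        voxel_len_um, volume_shape,
                        sample_points_um = (samples_vox - 1) * voxel_len_um)
  surf
}

# minimal Euclidean distance from each query point to a point set, chunked
nearest_distances <- function(queries, points) {
  nq <- nrow(queries)
  out <- numeric(nq)
  step <- max(1L, as.integer(2e6 / max(1L, nrow(points))))
  for (s in seq(1L, nq, by = step)) {
    e <- min(nq, s + step - 1L)
    q <- queries[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(points))) -
      2 * q %*% t(points) +
      outer(rep(1, nrow(q)), rowSums(points^2))
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# trilinear interpolation of a (g1, g2, g3, k) array at arbitrary positions
# given in the physical units of node_ax
interp_trilinear <- function(field, node_ax, pts) {
  g <- dim(field)[1:3]
  k <- dim(field)[4]
  # fractional node index per axis
  fr <- sapply(1:3, function(a) {
    x <- (pts[, a] - node_ax[[a]][1]) / (node_ax[[a]][2] - node_ax[[a]][1]) + 1
    pmin(pmax(x, 1), g[a])
  })
  i0 <- pmin(floor(fr), matrix(g - 1L, nrow(fr), 3, byrow = TRUE))
  w <- fr - i0
  out <- matrix(0, nrow(pts), k)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dz) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dx) w[, 3] else 1 - w[, 3])
    for (j in seq_len(k)) {
      out[, j] <- out[, j] + wt *
        field[cbind(i0[, 1] + dz, i0[, 2] + dy, i0[, 3] + dx, j)]
    }
  }
  out
}

#' Local and summary cell densities on the layer surface
#'
#' Per vertex, the local surface density is the number of cell centroids
#' within `density_radius_um` of the vertex's sheet-projected sampling
#' point, divided by the area of the corresponding disc
#' (\eqn{\pi r^2}), reported in cells/mm^2.
#'
#' Summary statistics: the area-weighted vertex mean of the local density,
#' computed with a minus-sampling edge correction -- near the dataset
#' border the counting disc extends beyond the sampled cell population and
#' the raw local density is biased low, so the mean is taken only over
#' vertices whose sampling point keeps `density_radius_um` clearance from
#' the population's bounding box along every axis on which the population
#' extends farther than the neighbourhood diameter (both the guarded and
#' the raw mean are reported). Also: the global surface density
#' `n_cells / (area_mm2 / 2)` (the closed offset surface has two sides)
#' and the volumetric density `n_cells` per ROI volume in mm^3.
#'
#' @param surface A [layer_surface()].
#' @param cells N x 3 centroid matrix in voxel coordinates.
#' @param p A [layer_params()] object.
#' @param cell_volumes_um3 Optional vector of per-cell volumes; its mean is
#'   recorded in the summary.
#' @return The surface with `density_mm2` (per vertex) and `summary` filled.
#' @export
local_density <- function(surface, cells, p, cell_volumes_um3 = NULL) {
  if (!inherits(surface, "layer_surface")) stop("expected a layer_surface")
  cells <- as_centroid_matrix(cells)
  cells_um <- (cells - 1) * surface$voxel_len_um
  r <- p$density_radius_um
  counts <- ball_counts(surface$sample_points_um, cells_um, r)
  density <- counts / (pi * r^2) * 1e6  # cells per mm^2
  # area-weighted vertex mean: each face contributes a third of its area
  # to each of its vertices
  wts <- numeric(nrow(surface$vertices_um))
  fa3 <- surface$face_areas_um2 / 3
  for (j in 1:3) {
    acc <- rowsum(fa3, surface$faces[, j])
    wts[as.integer(rownames(acc))] <- wts[as.integer(rownames(acc))] + acc[, 1]
  }
  # minus-sampling guard: keep vertices with full neighbourhood support
  guard <- rep(TRUE, nrow(surface$sample_points_um))
  for (a in 1:3) {
    rng <- range(cells_um[, a])
    if (diff(rng) > 2 * r) {
      guard <- guard & surface$sample_points_um[, a] >= rng[1] + r &
        surface$sample_points_um[, a] <= rng[2] - r
    }
  }
  if (!any(guard)) guard <- rep(TRUE, length(guard))  # degenerate geometry
  n_cells <- nrow(cells)
  vol_mm3 <- prod(surface$volume_shape) * surface$voxel_len_um^3 / 1e9
  surface$density_mm2 <- density
  surface$summary <- list(
    n_cells = n_cells,
    mean_density_per_mm2 = sum(density[guard] * wts[guard]) /
      sum(wts[guard]),
    mean_density_raw_per_mm2 = sum(density * wts) / sum(wts),
    n_guarded_vertices = sum(guard),
    global_density_per_mm2 = n_cells / (surface$area_mm2 / 2),
    volumetric_density_per_mm3 = n_cells / vol_mm3,
    mean_cell_volume_um3 = if (is.null(cell_volumes_um3)) NA_real_ else
      mean(cell_volumes_um3, na.rm = TRUE))
  surface
}

ball_counts <- function(queries, points, radius) {
  nq <- nrow(queries)
  if (nrow(points) == 0L) return(integer(nq))
  out <- integer(nq)
  step <- max(1L, as.integer(2e6 / nrow(points)))
  r2 <- radius^2
  for (s in seq(1L, nq, by = step)) {
    e <- min(nq, s + step - 1L)
    q <- queries[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(points))) -
      2 * q %*% t(points) +
      outer(rep(1, nrow(q)), rowSums(points^2))
    out[s:e] <- rowSums(d2 <= r2)
  }
  out
}

#' Write a layer surface as binary PLY
#'
#' Binary little-endian PLY with float vertex coordinates (x, y, z, in um)
#' and a per-vertex scalar property `density_mm2` (0 when densities have
#' not been computed).
#'
#' @param surface A [layer_surface()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surface, path) {
  v <- surface$vertices_um
  f <- surface$faces
  dens <- surface$density_mm2
  if (is.null(dens)) dens <- numeric(nrow(v))
  header <- c(
    "ply",
    "format binary_little_endian 1.0",
    "comment produced by purkinje3d (coordinates in micrometres)",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    "property float density_mm2",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  # (z, y, x) -> x, y, z
  vd <- t(cbind(v[, 3], v[, 2], v[, 1], dens))
  writeBin(as.vector(vd), con, size = 4, endian = "little")
  nf <- nrow(f)
  int_raw <- writeBin(as.integer(t(f) - 1L), raw(), size = 4,
                      endian = "little")
  block <- matrix(raw(), nrow = 13L, ncol = nf)
  block[1, ] <- as.raw(3L)
  block[2:13, ] <- matrix(int_raw, nrow = 12L)
  writeBin(as.vector(block), con)
  invisible(path)
}
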