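test_that("layer-population selection keeps the largest connected cube set", {
  p <- layer_params(grid_spacing_vox = 50)
  shape <- c(256, 256, 256)
  # all in one cube
  one <- cbind(z = c(10, 20, 30), y = c(10, 20, 30), x = c(10, 20, 30))
  expect_equal(nrow(select_layer_population(one, p, shape)), 3L)

  # a 30-cell cluster spanning adjacent cubes vs a 3-cell remote cluster
  set.seed(51)
  big <- cbind(runif(30, 1, 140), runif(30, 1, 90), runif(30, 1, 90))
  small <- cbind(runif(3, 210, 250), runif(3, 210, 250), runif(3, 210, 250))
  cells <- rbind(big, small)
  kept <- select_layer_population(cells, p, shape)
  expect_equal(nrow(kept), 30L)
  expect_true(all(attr(kept, "selected") <= 30))

  # exhaustive oracle: component of filled cubes containing the big cluster
  # (26-connected cube adjacency = Chebyshev distance 1)
  cube <- floor((cells - 1) / 50)
  key <- paste(cube[, 1], cube[, 2], cube[, 3])
  filled <- unique(cube)
  adj <- as.matrix(dist(filled, method = "maximum")) == 1
  comp <- rep(0L, nrow(filled)); cid <- 0L
  for (i in seq_len(nrow(filled))) {
    if (comp[i] > 0) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- which(adj[frontier[1], ] & comp == 0L)
      comp[nxt] <- cid
      frontier <- c(frontier[-1], nxt)
    }
  }
  best <- which.max(tabulate(comp))
  fkey <- paste(filled[, 1], filled[, 2], filled[, 3])
  oracle_keep <- which(comp[match(key, fkey)] == best)
  expect_equal(sort(attr(kept, "selected")), sort(oracle_keep))

  # idempotence and subset property
  again <- select_layer_population(kept, p, shape)
  expect_equal(nrow(again), nrow(kept))
  expect_equal(unname(as.matrix(again)), unname(as.matrix(kept)))
})

test_that("tie-breaking between equal components is deterministic", {
  p <- layer_params(grid_spacing_vox = 50)
  shape <- c(256, 256, 256)
  a <- c(25, 25, 25)     # cube (0,0,0)
  b <- c(225, 225, 225)  # far cube, same size component
  cells <- rbind(b, a)
  k1 <- select_layer_population(cells, p, shape)
  k2 <- select_layer_population(cells[c(2, 1), ], p, shape)
  expect_equal(nrow(k1), 1L)
  # the component containing the smallest linear cube index wins: cube of `a`
  expect_equal(as.numeric(k1[1, ]), a)
  expect_equal(as.numeric(k2[1, ]), a)
})

test_that("a dense cell plane yields two offset sheets at the zero level", {
  p <- layer_params(dist_grid_spacing_vox = 10, zero_level_vox = 44,
                    smoothing_sigma_nodes = 2)
  vl <- 1.75
  z0 <- 101
  g <- expand.grid(y = seq(11, 191, by = 20), x = seq(11, 191, by = 20))
  cells <- cbind(z = rep(z0, nrow(g)), y = g$y, x = g$x)
  surf <- extract_layer_surface(cells, p, c(211, 201, 201), vl)
  z_um <- surf$vertices_um[, 1]
  z0_um <- (z0 - 1) * vl
  # evaluate over the flat part of the offset slab: lateral positions well
  # inside the lattice footprint, away from the rounded rim
  lat_lo <- (11 - 1) * vl + 44 * vl
  lat_hi <- (191 - 1) * vl - 44 * vl
  flat <- surf$vertices_um[, 2] > lat_lo & surf$vertices_um[, 2] < lat_hi &
    surf$vertices_um[, 3] > lat_lo & surf$vertices_um[, 3] < lat_hi
  # split into the two sheets; each at |z - z0| ~ 44 voxels
  for (side in list(flat & z_um > z0_um, flat & z_um < z0_um)) {
    expect_gt(sum(side), 0)
    dev <- abs(mean(abs(z_um[side] - z0_um)) - 44 * vl) / (44 * vl)
    expect_lt(dev, 0.10)
  }
})

test_that("a single centroid yields a sphere with the closed-form area", {
  # light smoothing: the geometry check targets the marching surface, not
  # the smoothing bias of a strongly curved distance field
  p <- layer_params(dist_grid_spacing_vox = 10, zero_level_vox = 44,
                    smoothing_sigma_nodes = 0.5)
  vl <- 1.75
  cells <- cbind(z = 106, y = 106, x = 106)
  surf <- extract_layer_surface(cells, p, c(211, 211, 211), vl)
  a_true <- 4 * pi * (44 * vl)^2 / 1e6
  expect_lt(abs(surf$area_mm2 - a_true) / a_true, 0.15)
  # radii of all vertices close to the zero level
  r <- sqrt(rowSums(sweep(surf$vertices_um, 2, (c(106, 106, 106) - 1) * vl)^2))
  expect_lt(abs(mean(r) - 44 * vl) / (44 * vl), 0.10)
})

test_that("surface extraction is equivariant under coarse-grid translations", {
  p <- layer_params(dist_grid_spacing_vox = 10, zero_level_vox = 30,
                    smoothing_sigma_nodes = 1)
  vl <- 1.0
  set.seed(52)
  base <- cbind(z = runif(8, 95, 105), y = runif(8, 95, 125),
                x = runif(8, 95, 125))
  s1 <- extract_layer_surface(base, p, c(221, 221, 221), vl)
  shift <- c(10, 0, 0)
  s2 <- extract_layer_surface(sweep(base, 2, shift, "+"), p,
                              c(221, 221, 221), vl)
  v1 <- s1$vertices_um[order(s1$vertices_um[, 1], s1$vertices_um[, 2],
                             s1$vertices_um[, 3]), ]
  v2 <- sweep(s2$vertices_um, 2, shift * vl)
  v2 <- v2[order(v2[, 1], v2[, 2], v2[, 3]), ]
  expect_equal(dim(v1), dim(v2))
  expect_lt(max(abs(v1 - v2)), 1e-6)
})

test_that("extraction errors on empty input and missing zero crossings", {
  p <- layer_params()
  expect_error(extract_layer_surface(matrix(numeric(0), 0, 3), p,
                                     c(100, 100, 100), 1.75))
  # cells everywhere: distance never reaches the 44-voxel zero level
  g <- as.matrix(expand.grid(z = seq(6, 96, 10), y = seq(6, 96, 10),
                             x = seq(6, 96, 10)))
  expect_error(extract_layer_surface(g, p, c(101, 101, 101), 1.75),
               "zero crossing")
})

test_that("local density matches brute-force ball counting on a planar lattice", {
  # synthetic flat surface whose sample points coincide with its vertices
  side <- seq(0, 1600, by = 40)
  g <- as.matrix(expand.grid(y = side, x = side))
  nv <- nrow(g)
  verts <- cbind(z = rep(0, nv), y = g[, 1], x = g[, 2])
  # triangulate the grid
  n <- length(side)
  idx <- function(i, j) (j - 1) * n + i
  faces <- NULL
  for (j in 1:(n - 1)) for (i in 1:(n - 1)) {
    faces <- rbind(faces, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                   c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  surf <- layer_surface(verts, faces, voxel_len_um = 1.75,
                        volume_shape = c(10, 915, 915))
  # cells: 80 um lattice on the same plane (voxel coordinates)
  cside <- seq(0, 1600, by = 80)
  cg <- as.matrix(expand.grid(y = cside, x = cside))
  cells_vox <- cbind(z = 1, y = cg[, 1] / 1.75 + 1, x = cg[, 2] / 1.75 + 1)
  p <- layer_params(density_radius_um = 100)
  surf <- local_density(surf, cells_vox, p)
  # brute-force count oracle at every vertex
  cells_um <- (cells_vox - 1) * 1.75
  for (i in seq(1, nv, by = 97)) {
    cnt <- sum(rowSums(sweep(cells_um, 2, verts[i, ])^2) <= 100^2)
    expect_equal(surf$density_mm2[i], cnt / (pi * 100^2) * 1e6)
  }
  # interior density close to the analytic 1/(80 um)^2 = 156 cells/mm^2
  interior <- verts[, 2] > 300 & verts[, 2] < 1300 &
    verts[, 3] > 300 & verts[, 3] < 1300
  expect_lt(abs(mean(surf$density_mm2[interior]) - 156.25) / 156.25, 0.10)
  # zero cells near a vertex -> zero density
  far <- local_density(surf, cells_vox + 1e5, p)
  expect_true(all(far$density_mm2 == 0))
})

test_that("doubling coordinates and radius preserves counts and quarters densities", {
  set.seed(53)
  verts <- cbind(z = runif(40, 0, 100), y = runif(40, 0, 100),
                 x = runif(40, 0, 100))
  faces <- cbind(1:38, 2:39, 3:40)
  surf1 <- layer_surface(verts, faces, 1.0, c(100, 100, 100))
  cells <- cbind(z = runif(60, 0, 100), y = runif(60, 0, 100),
                 x = runif(60, 0, 100)) + 1
  d1 <- local_density(surf1, cells, layer_params(density_radius_um = 30))
  surf2 <- layer_surface(2 * verts, faces, 1.0, c(200, 200, 200))
  d2 <- local_density(surf2, 2 * (cells - 1) + 1,
                      layer_params(density_radius_um = 60))
  counts1 <- d1$density_mm2 * pi * 30^2 / 1e6
  counts2 <- d2$density_mm2 * pi * 60^2 / 1e6
  expect_equal(counts1, counts2, tolerance = 1e-9)
  expect_equal(d2$density_mm2, d1$density_mm2 / 4, tolerance = 1e-9)
})

test_that("PLY export writes a well-formed binary mesh", {
  verts <- cbind(z = c(0, 0, 10), y = c(0, 10, 0), x = c(0, 0, 0))
  surf <- layer_surface(verts, matrix(c(1, 2, 3), 1), 1.75, c(10, 10, 10))
  path <- file.path(tempdir(), "mesh.ply")
  write_ply(surf, path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  header_end <- grepRaw("end_header\n", bytes) + nchar("end_header\n") - 1
  expect_gt(header_end, 0)
  expect_equal(length(bytes) - header_end, 3 * 16 + 13)
  txt <- rawToChar(bytes[1:header_end])
  expect_match(txt, "element vertex 3")
  expect_match(txt, "property float density_mm2")
})
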