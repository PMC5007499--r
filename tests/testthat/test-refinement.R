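step_sphere_volume <- function(r_in = 5, inside = 0.8, outside = 0.2,
                               n = 17) {
  c0 <- (n + 1) / 2
  co <- 1:n
  r2 <- outer(outer((co - c0)^2, (co - c0)^2, "+"), (co - c0)^2, "+")
  list(volume = volume3d(array(ifelse(r2 <= r_in^2, inside, outside),
                               c(n, n, n)), 1.75),
       inside_mask = r2 <= r_in^2,
       c0 = c0)
}

test_that("Otsu's threshold equals the exhaustive between-class-variance search", {
  set.seed(41)
  cases <- list(
    c(rnorm(300, 0.3, 0.05), rnorm(80, 0.8, 0.05)),
    c(runif(200, 0, 0.4), runif(50, 0.7, 1)),
    c(rnorm(500, 0.5, 0.02), rnorm(5, 0.95, 0.01))
  )
  for (x in cases) {
    expect_equal(otsu_threshold(x, 128), oracle_otsu(x, 128),
                 tolerance = 1e-12)
  }
  # cross-check against an established independent implementation; the
  # between-class variance is flat across an empty histogram valley, so
  # compare the induced partitions rather than the tie-broken edge value
  x <- cases[[1]]
  x01 <- (x - min(x)) / (max(x) - min(x))
  ours <- otsu_threshold(x01, 256)
  ref <- EBImage::otsu(EBImage::Image(matrix(x01, 20)), range = c(0, 1),
                       levels = 256)
  expect_identical(x01 > ours, x01 > ref)
  expect_error(otsu_threshold(rep(0.4, 50)), "degenerate")
})

test_that("region growing recovers the step sphere exactly (BFS oracle)", {
  sc <- step_sphere_volume()
  seed <- mask_to_object(with(sc, {
    co <- 1:17
    r2 <- outer(outer((co - c0)^2, (co - c0)^2, "+"), (co - c0)^2, "+")
    r2 <= 3^2
  }))
  p <- refinement_params(max_intensity_distance = 0.0385,
                         growth_cap_vox = 5)
  grown <- region_grow(sc$volume, seed, p)
  grown_mask <- array(FALSE, dim(sc$volume$data))
  grown_mask[grown$coords] <- TRUE
  expect_identical(grown_mask, sc$inside_mask)
  # agreement with the independent BFS oracle
  seed_mask <- array(FALSE, dim(sc$volume$data))
  seed_mask[seed$coords] <- TRUE
  oracle <- oracle_region_grow(sc$volume$data, seed_mask, 0.0385, 5)
  expect_identical(grown_mask, oracle)
})

test_that("region growing fills exactly the cap region on a uniform volume", {
  v <- volume3d(array(0.5, c(15, 15, 15)), 1.75)
  seed_mask <- array(FALSE, c(15, 15, 15)); seed_mask[8, 8, 8] <- TRUE
  seed <- mask_to_object(seed_mask)
  grown <- region_grow(v, seed, refinement_params(growth_cap_vox = 4))
  co <- 1:15
  r2 <- outer(outer((co - 8)^2, (co - 8)^2, "+"), (co - 8)^2, "+")
  expected <- r2 <= 16
  grown_mask <- array(FALSE, c(15, 15, 15)); grown_mask[grown$coords] <- TRUE
  expect_identical(grown_mask, expected)
})

test_that("zero tolerance on strictly distinct intensities grows nothing", {
  set.seed(42)
  vals <- sample(seq(0, 1, length.out = 1000), 6^3)
  v <- volume3d(array(vals, c(6, 6, 6)), 1.75)
  seed_mask <- array(FALSE, c(6, 6, 6)); seed_mask[3, 3, 3] <- TRUE
  grown <- region_grow(v, mask_to_object(seed_mask),
                       refinement_params(max_intensity_distance = 0))
  expect_equal(grown$size_vox, 1L)
  expect_equal(grown$coords[1, ], c(z = 3L, y = 3L, x = 3L))
})

test_that("region growing is monotone in tolerance and idempotent at fixpoint", {
  sc <- step_sphere_volume()
  seed_mask <- array(FALSE, dim(sc$volume$data)); seed_mask[9, 9, 9] <- TRUE
  seed <- mask_to_object(seed_mask)
  sizes <- vapply(c(0.01, 0.05, 0.2, 0.7), function(tol) {
    region_grow(sc$volume, seed,
                refinement_params(max_intensity_distance = tol,
                                  growth_cap_vox = 6))$size_vox
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
  # subset relation, not only sizes
  g1 <- region_grow(sc$volume, seed,
                    refinement_params(max_intensity_distance = 0.05,
                                      growth_cap_vox = 6))
  g2 <- region_grow(sc$volume, seed,
                    refinement_params(max_intensity_distance = 0.2,
                                      growth_cap_vox = 6))
  k1 <- paste(g1$coords[, 1], g1$coords[, 2], g1$coords[, 3])
  k2 <- paste(g2$coords[, 1], g2$coords[, 2], g2$coords[, 3])
  expect_true(all(k1 %in% k2))

  # idempotence: re-growing the result under the original reference mean
  # adds nothing (the step boundary binds)
  ref <- mean(sc$volume$data[9, 9, 9])
  p <- refinement_params(max_intensity_distance = 0.0385,
                         growth_cap_vox = 6)
  once <- region_grow(sc$volume, seed, p)
  twice <- region_grow(sc$volume, once, p, reference_mean = ref)
  expect_equal(twice$size_vox, once$size_vox)
})

test_that("nucleolus segmentation recovers a planted bright sphere", {
  n <- 21; c0 <- 11
  co <- 1:n
  r2 <- outer(outer((co - c0)^2, (co - c0)^2, "+"), (co - c0)^2, "+")
  vol <- array(0.1, c(n, n, n))
  vol[r2 <= 8^2] <- 0.6                # soma
  vol[r2 <= 2^2] <- 1.0                # nucleolus
  v <- volume3d(vol, 1.75)
  cell <- mask_to_object(r2 <= 8^2)
  nuc <- segment_nucleolus(v, cell)
  planted <- which(r2 <= 2^2)
  got <- nuc$coords[, 1] + (nuc$coords[, 2] - 1) * n +
    (nuc$coords[, 3] - 1) * n * n
  expect_setequal(got, planted)
  expect_equal(unname(nuc$centroid), c(c0, c0, c0))
  expect_equal(nuc$volume_um3, sum(r2 <= 4) * 1.75^3)

  # uniform cell: degenerate histogram
  flat <- volume3d(array(0.5, c(9, 9, 9)), 1.75)
  cell2 <- mask_to_object(array(TRUE, c(9, 9, 9)))
  expect_error(segment_nucleolus(flat, cell2), "degenerate")
})

test_that("the nucleolus seed tie-break is lexicographic in (z, y, x)", {
  vol <- array(0.2, c(6, 6, 6))
  vol[2, 5, 3] <- 0.9
  vol[4, 1, 2] <- 0.9      # tie; smaller z wins
  v <- volume3d(vol, 1)
  cell <- mask_to_object(array(TRUE, c(6, 6, 6)))
  nuc <- segment_nucleolus(v, cell)
  expect_equal(unname(nuc$seed), c(2L, 5L, 3L))
})

test_that("refine_cells produces the cell table with physical volumes", {
  n <- 25; c0 <- 13
  co <- 1:n
  r2 <- outer(outer((co - c0)^2, (co - c0)^2, "+"), (co - c0)^2, "+")
  vol <- array(0.2, c(n, n, n))
  vol[r2 <= 6^2] <- 0.6
  vol[r2 <= 1.5^2] <- 0.95
  v <- volume3d(vol, 1.75)
  seed <- mask_to_object(r2 <= 4^2)
  seed$cls <- "cell_candidate"
  cells <- refine_cells(v, list(seed), refinement_params(growth_cap_vox = 4))
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$volume_um3, sum(r2 <= 36) * 1.75^3)
  expect_equal(c(cells$nucleolus_z, cells$nucleolus_y, cells$nucleolus_x),
               c(c0, c0, c0))
})
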