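response_from_mask <- function(mask, voxel_len_um = 1.75) {
  volume3d(array(as.numeric(mask), dim(mask)), voxel_len_um)
}

test_that("extract_objects returns an empty list on an all-zero response", {
  resp <- volume3d(array(0, c(12, 12, 12)), 1.75)
  objs <- extract_objects(resp)
  expect_length(objs, 0)
  expect_true(all(attr(objs, "label_array") == 0L))
})

test_that("the size gate excludes strictly below 300 and above 3000 voxels", {
  # four objects with exactly 299 / 300 / 3000 / 3001 voxels
  d <- c(40, 60, 80)
  mask <- array(FALSE, d)
  mask[2:14, 2:24, 2] <- TRUE                    # 13 * 23     = 299
  mask[2:16, 2:21, 6] <- TRUE                    # 15 * 20     = 300
  mask[2:16, 2:21, 10:19] <- TRUE                # 15 * 20 * 10 = 3000
  mask[2:16, 2:21, 23:32] <- TRUE                # 3000 ...
  mask[17, 21, 23] <- TRUE                       # ... + 1, face-adjacent
  p <- segmentation_params(response_threshold = 0.5, border_margin_vox = 0)
  objs <- extract_objects(response_from_mask(mask), p)
  sizes <- sort(vapply(objs, function(o) o$size_vox, integer(1)))
  expect_equal(sizes, c(299L, 300L, 3000L, 3001L))
  cls <- vapply(objs, function(o) o$cls, character(1))
  expect_equal(cls[order(vapply(objs, function(o) o$size_vox, integer(1)))],
               c("rejected_size", NA, NA, "rejected_size"))
})

test_that("component extraction matches the brute-force flood-fill oracle", {
  set.seed(31)
  d <- c(18, 18, 18)
  resp <- array(0, d)
  resp[3:7, 3:7, 3:7] <- 1                       # 125-voxel blob
  resp[11:15, 11:15, 10:15] <- 1                 # 150-voxel blob
  speck <- cbind(sample(17:18, 30, TRUE), sample(18, 30, TRUE),
                 sample(18, 30, TRUE))           # speckle clear of the blobs
  resp[speck] <- 1
  rv <- volume3d(resp, 1.75)
  p <- segmentation_params(response_threshold = 0.5, min_size_vox = 100,
                           max_size_vox = 140, border_margin_vox = 0)
  objs <- extract_objects(rv, p, fill_holes = FALSE)
  lab_oracle <- oracle_label26(resp > 0.5)
  expect_length(objs, max(lab_oracle))
  sizes <- sort(vapply(objs, function(o) o$size_vox, integer(1)))
  expect_equal(sizes, sort(as.integer(table(lab_oracle[lab_oracle > 0]))))
  # partition: object sizes sum to the above-threshold voxel count and
  # every above-threshold voxel carries exactly one label
  la <- attr(objs, "label_array")
  expect_equal(sum(vapply(objs, function(o) o$size_vox, integer(1))),
               sum(resp > 0.5))
  expect_true(all((la > 0) == (resp > 0.5)))
  # the 125-voxel interior blob survives the [100, 140] gate, the others not
  surv <- Filter(function(o) is.na(o$cls), objs)
  expect_length(surv, 1)
  expect_equal(surv[[1]]$size_vox, 125L)
})

test_that("border-margin rejection tags objects touching the outer margin", {
  d <- c(40, 40, 40)
  mask <- array(FALSE, d)
  mask[5:12, 15:24, 15:24] <- TRUE     # touches z margin (z = 5 <= 10)
  mask[20:27, 15:24, 15:24] <- TRUE    # interior
  p <- segmentation_params(response_threshold = 0.5, min_size_vox = 100,
                           max_size_vox = 5000, border_margin_vox = 10)
  objs <- extract_objects(response_from_mask(mask), p)
  cls <- vapply(objs, function(o) o$cls, character(1))
  z1 <- vapply(objs, function(o) min(o$coords[, 1]), integer(1))
  expect_equal(cls[z1 == 5L], "rejected_border")
  expect_true(is.na(cls[z1 == 20L]))
})

test_that("mean level-set values match the exact-EDT brute force on balls and tubes", {
  # degenerate object: a single voxel is 1 away from background
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(mean_level_set_value(mask_to_object(single)), -1)

  ball <- ball_mask(8)
  obj <- mask_to_object(ball)
  mlv <- mean_level_set_value(obj)
  expect_equal(mlv, oracle_mean_inside_distance(ball), tolerance = 1e-12)
  # continuum limit R/4 bounds the digital value
  expect_lt(abs(abs(mlv) - 8 / 4) / (8 / 4), 0.3)

  tube <- tube_mask(3, 60)
  objt <- mask_to_object(tube)
  mlvt <- mean_level_set_value(objt)
  expect_equal(mlvt, oracle_mean_inside_distance(tube), tolerance = 1e-12)
  # continuum limit r/3 for a long tube
  expect_lt(abs(abs(mlvt) - 1) / 1, 0.6)
})

test_that("classification applies the sphere rule before the tube rule", {
  # a radius-50 ball has |mean_lsv| ~ 13 > 12 -> corpus with the published
  # threshold, even though its size/lsv^2 is far above the vessel rule
  ball <- ball_mask(50, pad = 1)
  obj <- mask_to_object(ball)
  p <- segmentation_params(min_size_vox = 1, max_size_vox = 1e6)
  cl <- classify_objects(list(obj), p)[[1]]
  expect_gt(abs(cl$mean_lsv), 12)
  expect_gt(cl$tube_ratio, 450)
  expect_equal(cl$cls, "corpus")
})

test_that("tubes classify as vessels and compact cell-sized objects as candidates", {
  p <- segmentation_params()
  tube <- tube_mask(3, 60)
  cl <- classify_objects(list(mask_to_object(tube)), p)[[1]]
  expect_lt(abs(cl$mean_lsv), 12)
  expect_gt(cl$tube_ratio, 450)
  expect_equal(cl$cls, "vessel")

  ball <- ball_mask(6)    # ~905 voxels, the soma reference size
  cl2 <- classify_objects(list(mask_to_object(ball)), p)[[1]]
  expect_lte(cl2$tube_ratio, 450)
  expect_equal(cl2$cls, "cell_candidate")

  # rule arithmetic: |mean_lsv| = 2 and size 900 gives ratio 225 <= 450
  expect_equal(900 / 2^2, 225)

  # determinism / order-independence
  both <- classify_objects(list(mask_to_object(tube), mask_to_object(ball)), p)
  both_rev <- classify_objects(list(mask_to_object(ball),
                                    mask_to_object(tube)), p)
  expect_equal(both[[1]]$cls, both_rev[[2]]$cls)
  expect_equal(both[[2]]$cls, both_rev[[1]]$cls)
})

test_that("hole filling closes cavities without touching open background", {
  m <- array(FALSE, c(12, 12, 12))
  m[3:9, 3:9, 3:9] <- TRUE
  m[5:7, 5:7, 5:7] <- FALSE          # internal cavity
  m[1, 1, ] <- FALSE                 # open background stays
  filled <- fill_holes3d(m)
  expect_true(all(filled[5:7, 5:7, 5:7]))
  expect_false(any(filled[1, 1, ]))
  expect_equal(sum(filled), sum(m) + 27)
})

test_that("segment_dendrite returns the largest tube tree and merges an overlapping soma", {
  fx <- phantom_dendrite_cell(shape = c(72, 72, 72), include_second_tree = TRUE)
  dp <- dendrite_mode_params(scales_vox = 1:3)
  obj <- segment_dendrite(fx$volume, dendrite_params = dp,
                          response_threshold = 0.1)
  # the returned object is the main tree: it reaches the trunk region well
  # above the soma and stays out of the second tree's corner
  expect_gt(obj$size_vox, 500)
  expect_lt(min(obj$coords[, 1]), fx$truth$soma_centre_vox[1] - 20)
  in_corner <- obj$coords[, 2] < 0.25 * 72 & obj$coords[, 3] > 0.7 * 72
  expect_equal(sum(in_corner), 0L)

  # voxel-identical to brute-force largest-component selection
  resp <- frangi_response(fx$volume, dp)
  lab <- oracle_label26(resp$data > 0.1)
  sizes <- table(lab[lab > 0])
  expect_equal(obj$size_vox, as.integer(max(sizes)))

  # empty response errors
  flat <- volume3d(array(0.5, c(24, 24, 24)), 0.45)
  expect_error(segment_dendrite(flat, dendrite_params = dp), "no object")
})
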