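#' Parameters for cell-mask refinement
#'
#' Region growing extends a detected object to all 26-connected voxels whose
#' intensity lies within `max_intensity_distance` of the seed's mean
#' intensity (default 0.0385 on the normalised `[0, 1]` scale, the published
#' tolerance). Growth is capped at `growth_cap_vox` Euclidean voxels from
#' the seed mask: unbounded tolerance growing leaks through low-contrast
#' boundaries in noisy data, so the cap keeps growth local. The nucleolus is
#' thresholded inside each cell with Otsu's method on a histogram with
#' `otsu_bins` bins.
#'
#' @param max_intensity_distance Intensity tolerance (>= 0), on `[0, 1]`.
#' @param growth_cap_vox Maximal Euclidean growth distance from the seed
#'   mask, voxels (>= 0).
#' @param otsu_bins Number of histogram bins for Otsu (>= 2).
#' @return An object of class `refinement_params`.
#' @export
refinement_params <- function(max_intensity_distance = 0.0385,
                              growth_cap_vox = 5, otsu_bins = 256) {
  if (max_intensity_distance < 0) stop("tolerance must be >= 0")
  if (growth_cap_vox < 0) stop("`growth_cap_vox` must be >= 0")
  if (otsu_bins < 2) stop("`otsu_bins` must be >= 2")
  structure(list(max_intensity_distance = max_intensity_distance,
                 growth_cap_vox = growth_cap_vox,
                 otsu_bins = as.integer(otsu_bins)),
            class = "refinement_params")
}

coords_to_linear <- function(coords, d) {
  (coords[, 3] - 1L) * (d[1] * d[2]) + (coords[, 2] - 1L) * d[1] + coords[, 1]
}

#' Region growing with a fixed intensity tolerance
#'
#' Starting from the seed mask, all 26-connected voxels whose intensity lies
#' within `p$max_intensity_distance` of the seed's mean intensity are added
#' until a fixpoint, restricted to within `p$growth_cap_vox` Euclidean
#' voxels of the seed mask. The reference intensity is the initial seed mean
#' and is not updated during growth (an updating mean lets the region drift
#' and need not reach a fixpoint); it can be overridden via
#' `reference_mean`, e.g. to re-grow a previous result under its original
#' reference. The result always contains the seed.
#'
#' @param v A normalised [volume3d].
#' @param seed A non-empty `segmented_object`.
#' @param p A [refinement_params()] object.
#' @param reference_mean Optional reference intensity; defaults to the mean
#'   intensity over the seed voxels.
#' @return A `segmented_object` covering the grown mask (class `"cell"`).
#' @export
region_grow <- function(v, seed, p = refinement_params(),
                        reference_mean = NULL) {
  stop_if_not_volume(v)
  if (!inherits(seed, "segmented_object")) stop("`seed` must be a segmented_object")
  if (seed$size_vox == 0L) stop("empty seed")
  d <- dim(v$data)
  cap <- p$growth_cap_vox
  pad <- as.integer(ceiling(cap)) + 1L
  lo <- pmax(apply(seed$coords, 2, min) - pad, 1L)
  hi <- pmin(apply(seed$coords, 2, max) + pad, d)
  dd <- hi - lo + 1L
  sub <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sc <- cbind(seed$coords[, 1] - lo[1] + 1L,
              seed$coords[, 2] - lo[2] + 1L,
              seed$coords[, 3] - lo[3] + 1L)
  seed_mask <- array(FALSE, dd)
  seed_mask[sc] <- TRUE
  if (is.null(reference_mean)) reference_mean <- mean(sub[sc])
  dist2 <- .cpp_edt_sq(as.vector(seed_mask), dd)
  allowed <- (abs(sub - reference_mean) <= p$max_intensity_distance) &
    (dist2 <= cap^2)
  grow_mask <- allowed | seed_mask
  labels <- .cpp_label3d(as.vector(grow_mask), dd, 26L)
  seed_labels <- unique(labels[as.vector(seed_mask)])
  keep <- which(labels %in% seed_labels)
  coords_sub <- arrayInd(keep, dd)
  coords <- cbind(coords_sub[, 1] + lo[1] - 1L,
                  coords_sub[, 2] + lo[2] - 1L,
                  coords_sub[, 3] + lo[3] - 1L)
  out <- new_segmented_object(seed$label, coords, d, v$voxel_len_um,
                              cls = "cell")
  out
}

#' Otsu's threshold on a numeric sample
#'
#' Histogram-based Otsu threshold: the value among the `bins - 1` interior
#' bin edges that maximises the between-class variance (equivalently,
#' minimises the within-class variance). Ties resolve to the lowest edge.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold value; foreground is `x > threshold`.
#' @export
otsu_threshold <- function(x, bins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (length(x) == 0L || r[1] == r[2])
    stop("degenerate histogram: all intensities equal")
  bins <- as.integer(bins)
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(cnt)
  m0 <- cumsum(cnt * mids)
  total <- w0[bins]; mtot <- m0[bins]
  k <- seq_len(bins - 1L)
  w1 <- total - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sb <- rep(-Inf, bins - 1L)
  sb[valid] <- w0[k][valid] * w1[valid] *
    (m0[k][valid] / w0[k][valid] - (mtot - m0[k][valid]) / w1[valid])^2
  edges[which.max(sb) + 1L]
}

#' Locate and segment the nucleolus inside a cell mask
#'
#' The nucleolus appears as the maximal phase shift inside a segmented
#' Purkinje cell: the seed is the brightest voxel of the cell mask (ties
#' broken by lexicographic (z, y, x) order), Otsu's threshold is computed
#' on the in-mask intensity histogram, and the nucleolus mask is the
#' 26-connected component of above-threshold in-mask voxels containing the
#' seed.
#'
#' @param v A [volume3d].
#' @param cell A `segmented_object` holding the (refined) cell mask.
#' @param p A [refinement_params()] object (`otsu_bins` is used).
#' @return A list with `seed` (voxel triple of the intensity maximum),
#'   `centroid` (mask centroid), `coords` (mask voxels),
#'   `volume_um3`, and `threshold`.
#' @export
segment_nucleolus <- function(v, cell, p = refinement_params()) {
  stop_if_not_volume(v)
  if (!inherits(cell, "segmented_object")) stop("`cell` must be a segmented_object")
  if (cell$size_vox == 0L) stop("empty cell mask")
  d <- dim(v$data)
  vals <- v$data[cell$coords]
  if (max(vals) == min(vals))
    stop("degenerate histogram: uniform intensity inside the cell mask")
  mx <- max(vals)
  ties <- which(vals == mx)
  tc <- cell$coords[ties, , drop = FALSE]
  ord <- order(tc[, 1], tc[, 2], tc[, 3])
  seed <- tc[ord[1], ]
  thr <- otsu_threshold(vals, p$otsu_bins)
  above <- vals > thr
  # component containing the seed, on the cell's bounding box
  lo <- apply(cell$coords, 2, min)
  hi <- apply(cell$coords, 2, max)
  dd <- hi - lo + 1L
  m <- array(FALSE, dd)
  ac <- cell$coords[above, , drop = FALSE]
  m[cbind(ac[, 1] - lo[1] + 1L, ac[, 2] - lo[2] + 1L,
          ac[, 3] - lo[3] + 1L)] <- TRUE
  labels <- .cpp_label3d(as.vector(m), dd, 26L)
  dim(labels) <- dd
  seed_lab <- labels[seed[1] - lo[1] + 1L, seed[2] - lo[2] + 1L,
                     seed[3] - lo[3] + 1L]
  keep <- which(labels == seed_lab)
  cs <- arrayInd(keep, dd)
  coords <- cbind(z = cs[, 1] + lo[1] - 1L, y = cs[, 2] + lo[2] - 1L,
                  x = cs[, 3] + lo[3] - 1L)
  list(seed = seed, centroid = colMeans(coords), coords = coords,
       volume_um3 = nrow(coords) * v$voxel_len_um^3, threshold = thr)
}

#' Refine all cell candidates and build the cell table
#'
#' For every `cell_candidate` object, the mask is refined by
#' [region_grow()] and the nucleolus segmented with [segment_nucleolus()];
#' physical volumes are voxel counts times `voxel_len_um^3`.
#'
#' @param v The normalised intensity [volume3d] the objects were detected in.
#' @param objs Classified object list from [classify_objects()].
#' @param p A [refinement_params()] object.
#' @return A data.frame with one row per cell: `label`, refined centroid
#'   (`z`, `y`, `x`, voxels), `volume_um3`, nucleolus centroid and
#'   `nucleolus_volume_um3` (NA when the nucleolus histogram is
#'   degenerate). The refined masks are attached as attribute `masks`.
#' @export
refine_cells <- function(v, objs, p = refinement_params()) {
  cells <- Filter(function(o) identical(o$cls, "cell_candidate"), objs)
  rows <- vector("list", length(cells))
  masks <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    g <- region_grow(v, cells[[i]], p)
    masks[[i]] <- g
    nuc <- tryCatch(segment_nucleolus(v, g, p), error = function(e) NULL)
    rows[[i]] <- data.frame(
      label = g$label,
      z = g$centroid[1], y = g$centroid[2], x = g$centroid[3],
      volume_um3 = g$size_vox * v$voxel_len_um^3,
      nucleolus_z = if (is.null(nuc)) NA_real_ else nuc$centroid[1],
      nucleolus_y = if (is.null(nuc)) NA_real_ else nuc$centroid[2],
      nucleolus_x = if (is.null(nuc)) NA_real_ else nuc$centroid[3],
      nucleolus_volume_um3 = if (is.null(nuc)) NA_real_ else nuc$volume_um3,
      row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), z = numeric(), y = numeric(),
               x = numeric(), volume_um3 = numeric(),
               nucleolus_z = numeric(), nucleolus_y = numeric(),
               nucleolus_x = numeric(), nucleolus_volume_um3 = numeric())
  attr(out, "masks") <- masks
  out
}
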