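# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (loops, exhaustive search) so it cannot share a bug
# with the optimised implementation paths it checks.

# digital ball mask centred in a cube
ball_mask <- function(radius, pad = 2) {
  n <- 2 * (radius + pad) + 1
  c0 <- radius + pad + 1
  co <- seq_len(n)
  r2 <- outer(outer((co - c0)^2, (co - c0)^2, "+"), (co - c0)^2, "+")
  r2 <= radius^2
}

# digital tube of given radius along the x axis, fully interior
tube_mask <- function(radius, length, pad = 2) {
  side <- 2 * (radius + pad) + 1
  c0 <- radius + pad + 1
  co <- seq_len(side)
  r2 <- outer((co - c0)^2, (co - c0)^2, "+")
  disc <- r2 <= radius^2
  m <- array(FALSE, c(side, side, length + 2 * pad))
  for (x in pad + seq_len(length)) m[, , x] <- disc
  m
}

# exact mean signed distance over mask voxels: for every inside voxel,
# minimal Euclidean distance to any background voxel centre (O(n_in * n_bg))
oracle_mean_inside_distance <- function(mask) {
  d <- dim(mask)
  inside <- which(mask)
  outside <- which(!mask)
  ic <- arrayInd(inside, d)
  oc <- arrayInd(outside, d)
  dmin <- vapply(seq_len(nrow(ic)), function(i) {
    sqrt(min((oc[, 1] - ic[i, 1])^2 + (oc[, 2] - ic[i, 2])^2 +
               (oc[, 3] - ic[i, 3])^2))
  }, numeric(1))
  -mean(dmin)
}

# brute-force 26-connected flood fill labelling
oracle_label26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_of <- function(p) p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(start, d)[1, ])
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        qi <- idx_of(q)
        if (mask[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# exhaustive-search Otsu: maximise between-class variance over bin edges
oracle_otsu <- function(x, bins = 256) {
  r <- range(x)
  edges <- seq(r[1], r[2], length.out = bins + 1)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), bins)
  best <- -Inf; best_edge <- NA
  for (k in 1:(bins - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):bins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1):bins] * mids[(k + 1):bins]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_edge <- edges[k + 1] }
  }
  best_edge
}

# breadth-first region growing oracle: 26-neighbours within tolerance of the
# fixed seed mean, capped at Euclidean distance `cap` from the seed mask
oracle_region_grow <- function(vol, seed_mask, tol, cap) {
  d <- dim(vol)
  seed_idx <- which(seed_mask)
  sc <- arrayInd(seed_idx, d)
  ref <- mean(vol[seed_idx])
  capdist <- function(p) {
    sqrt(min((sc[, 1] - p[1])^2 + (sc[, 2] - p[2])^2 + (sc[, 3] - p[3])^2))
  }
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  accepted <- seed_mask
  queue <- lapply(seq_len(nrow(sc)), function(i) sc[i, ])
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(offs))) {
      q <- p + offs[k, ]
      if (any(q < 1) || any(q > d)) next
      qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
      if (accepted[qi]) next
      if (abs(vol[qi] - ref) > tol) next
      if (capdist(q) > cap) next
      accepted[qi] <- TRUE
      queue[[length(queue) + 1L]] <- q
    }
  }
  accepted
}

# exhaustive maximal matching under a radius (optimal assignment by
# recursion over the small detection set)
oracle_max_matching <- function(detected, truth, radius) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(0L)
  d2 <- as.matrix(dist(rbind(detected, truth)))[1:nd, nd + (1:nt),
                                                drop = FALSE]
  ok <- d2 <= radius
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)  # leave detection i unmatched
    for (j in which(ok[i, ])) {
      if (!used[j]) {
        used2 <- used; used2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, nt))
}

# segmented_object wrapper for a logical mask (test convenience)
mask_to_object <- function(mask, voxel_len_um = 1.75, label = 1L) {
  coords <- arrayInd(which(mask), dim(mask))
  purkinje3d:::new_segmented_object(label, coords, dim(mask), voxel_len_um)
}

# small deterministic random volume
rand_volume <- function(d = c(16, 16, 16), seed = 1, voxel_len_um = 1.0) {
  set.seed(seed)
  volume3d(array(runif(prod(d)), d), voxel_len_um)
}
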