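#' Configuration of the synthetic cerebellum phantom
#'
#' The phantom emulates the geometry and contrast of a paraffin-embedded
#' cerebellum tomogram at desk scale: a folded Purkinje-cell layer
#' (a sine sheet \eqn{z = z_0 + A \sin(2\pi x/L_x)\sin(2\pi y/L_y)})
#' separating the granular stratum (below) from the molecular stratum
#' (above), with paraffin on top; somata as smooth-edged bright spheres
#' placed on the sheet by dart throwing, each with a small brighter
#' nucleolar sphere at its centre; tubular vessels as persistent random
#' walks through the tissue; Corpora amylacea as small bright spheres away
#' from the layer; smooth linear and radial background gradients (the
#' local-tomography artefact); and Gaussian noise calibrated so the
#' measured signal-to-noise ratio (molecular vs paraffin) matches
#' `target_snr`.
#'
#' Defaults reproduce the study conditions at 1.75 um voxels: 165 cells per
#' mm^2 of layer, soma radius 10.5 um (volume 4/3 pi 10.5^3 = 4849 um^3,
#' i.e. about 905 voxels, inside the 300-3000 voxel detection gate),
#' SNR 13. Somata are kept at least `border_clear_vox` voxels away from
#' the volume faces so that the border rejection margin cannot clip
#' planted cells.
#'
#' @param shape Volume shape (z, y, x) in voxels.
#' @param voxel_len_um Isotropic voxel length (um).
#' @param layer List: `amplitude_um`, `wavelengths_um` (x and y),
#'   `z0_offset_um` (offset of the mid-plane from the volume centre).
#' @param cell_density_per_mm2 Target surface density of somata.
#' @param min_spacing_factor Dart-throwing minimum spacing =
#'   `min_spacing_factor / sqrt(density)` (in mm).
#' @param soma_radius_um,soma_intensity Soma geometry and intensity.
#' @param nucleolus_radius_um,nucleolus_intensity Nucleolus geometry and
#'   intensity (must be brighter than the soma, radius smaller).
#' @param n_vessels,vessel_radius_um Number of vessels and radius range (um).
#' @param n_corpora,corpus_radius_um,corpus_intensity Corpora amylacea
#'   count, radius range (um) and intensity.
#' @param intensities List of stratum intensities: `paraffin`, `molecular`,
#'   `granular` (nominal [0, 1] scale).
#' @param molecular_thickness_um Thickness of the molecular stratum (um).
#' @param background List: `linear` and `radial` gradient amplitudes.
#' @param target_snr Target SNR, |molecular - paraffin| / noise sd.
#' @param border_clear_vox Minimal clearance of soma surfaces from the
#'   volume faces (voxels).
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(256, 256, 256), voxel_len_um = 1.75,
                           layer = list(amplitude_um = 45,
                                        wavelengths_um = c(450, 450),
                                        z0_offset_um = 0),
                           cell_density_per_mm2 = 165,
                           min_spacing_factor = 0.7,
                           soma_radius_um = 10.5, soma_intensity = 0.62,
                           nucleolus_radius_um = 1.5,
                           nucleolus_intensity = 0.85,
                           n_vessels = 3, vessel_radius_um = c(3.5, 6),
                           n_corpora = 8, corpus_radius_um = c(2.5, 4),
                           corpus_intensity = 0.75,
                           intensities = list(paraffin = 0.20,
                                              molecular = 0.40,
                                              granular = 0.52),
                           molecular_thickness_um = 100,
                           background = list(linear = 0.02, radial = 0.03),
                           target_snr = 13, border_clear_vox = 20,
                           rng_seed = 42) {
  if (any(shape < 8)) stop("phantom shape must be at least 8 voxels per axis")
  if (voxel_len_um <= 0) stop("`voxel_len_um` must be > 0")
  if (cell_density_per_mm2 < 0) stop("`cell_density_per_mm2` must be >= 0")
  if (soma_radius_um <= 0 || nucleolus_radius_um <= 0)
    stop("radii must be > 0")
  if (nucleolus_radius_um >= soma_radius_um)
    stop("`nucleolus_radius_um` must be smaller than `soma_radius_um`")
  if (nucleolus_intensity <= soma_intensity)
    stop("`nucleolus_intensity` must exceed `soma_intensity`")
  if (target_snr <= 0) stop("`target_snr` must be > 0")
  structure(list(shape = as.integer(shape), voxel_len_um = voxel_len_um,
                 layer = layer,
                 cell_density_per_mm2 = cell_density_per_mm2,
                 min_spacing_factor = min_spacing_factor,
                 soma_radius_um = soma_radius_um,
                 soma_intensity = soma_intensity,
                 nucleolus_radius_um = nucleolus_radius_um,
                 nucleolus_intensity = nucleolus_intensity,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_um = vessel_radius_um,
                 n_corpora = as.integer(n_corpora),
                 corpus_radius_um = corpus_radius_um,
                 corpus_intensity = corpus_intensity,
                 intensities = intensities,
                 molecular_thickness_um = molecular_thickness_um,
                 background = background, target_snr = target_snr,
                 border_clear_vox = as.integer(border_clear_vox),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

# layer surface height (voxel z, 1-based) at micrometre lateral positions
phantom_surface_z_vox <- function(cfg, x_um, y_um) {
  vl <- cfg$voxel_len_um
  z0 <- (cfg$shape[1] + 1) / 2 + cfg$layer$z0_offset_um / vl
  A <- cfg$layer$amplitude_um / vl
  Lx <- cfg$layer$wavelengths_um[1]
  Ly <- cfg$layer$wavelengths_um[2]
  z0 + A * sin(2 * pi * x_um / Lx) * sin(2 * pi * y_um / Ly)
}

#' Analytic area of the phantom's layer sheet
#'
#' Area of the sine sheet over the cell-placement domain (the lateral
#' extent minus the border clearance), by fine-grid quadrature of
#' \eqn{\sqrt{1 + z_x^2 + z_y^2}}.
#'
#' @param cfg A [phantom_config()].
#' @param n_quad Quadrature grid size per axis.
#' @return Area in mm^2.
#' @export
phantom_layer_area_mm2 <- function(cfg, n_quad = 400) {
  vl <- cfg$voxel_len_um
  clear_um <- cfg$border_clear_vox * vl
  ext_y <- (cfg$shape[2] - 1) * vl
  ext_x <- (cfg$shape[3] - 1) * vl
  xs <- seq(clear_um, ext_x - clear_um, length.out = n_quad)
  ys <- seq(clear_um, ext_y - clear_um, length.out = n_quad)
  A <- cfg$layer$amplitude_um
  Lx <- cfg$layer$wavelengths_um[1]
  Ly <- cfg$layer$wavelengths_um[2]
  zx <- outer(ys, xs, function(y, x)
    A * (2 * pi / Lx) * cos(2 * pi * x / Lx) * sin(2 * pi * y / Ly))
  zy <- outer(ys, xs, function(y, x)
    A * (2 * pi / Ly) * sin(2 * pi * x / Lx) * cos(2 * pi * y / Ly))
  integrand <- sqrt(1 + zx^2 + zy^2)
  dx <- diff(xs)[1]; dy <- diff(ys)[1]
  sum(integrand) * dx * dy / 1e6  # um^2 -> mm^2
}

# blend a smooth-edged sphere into the volume (1-voxel intensity ramp)
stamp_sphere <- function(vol, centre_vox, radius_vox, intensity) {
  d <- dim(vol)
  lo <- pmax(floor(centre_vox - radius_vox - 2), 1)
  hi <- pmin(ceiling(centre_vox + radius_vox + 2), d)
  if (any(lo > hi)) return(vol)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  r2 <- outer(outer((zs - centre_vox[1])^2, (ys - centre_vox[2])^2, "+"),
              (xs - centre_vox[3])^2, "+")
  w <- pmin(pmax(radius_vox - sqrt(r2) + 0.5, 0), 1)
  vol[zs, ys, xs] <- vol[zs, ys, xs] * (1 - w) + intensity * w
  vol
}

#' Generate a synthetic cerebellum phantom with ground truth
#'
#' See [phantom_config()] for the scene model. Generation is fully
#' deterministic for a fixed `rng_seed`. Cells are placed on the layer
#' sheet by dart throwing with a minimum spacing of
#' `min_spacing_factor / sqrt(density)`; an error is raised if the
#' requested density cannot be realised after bounded retries. Somata
#' never overlap each other, vessels keep clear of somata, and each
#' nucleolus lies strictly inside its soma.
#'
#' @param cfg A [phantom_config()].
#' @return A list with `volume` (a [volume3d]) and `truth` (a data.frame
#'   of class `phantom_truth`: `class`, centroid `z`, `y`, `x` in voxel
#'   coordinates, `param1` (radius, um), `param2` (vessel path length,
#'   um; NA otherwise) and nucleolus centroid columns for cells).
#' @export
phantom_generate <- function(cfg) {
  if (!inherits(cfg, "phantom_config")) stop("`cfg` must be a phantom_config")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$rng_seed)

  d <- cfg$shape
  vl <- cfg$voxel_len_um
  ints <- cfg$intensities
  y_um <- (seq_len(d[2]) - 1) * vl
  x_um <- (seq_len(d[3]) - 1) * vl
  zs_mat <- outer(y_um, x_um, function(y, x) phantom_surface_z_vox(cfg, x, y))

  # strata: granular below the sheet, molecular above, paraffin on top
  vol <- array(ints$granular, d)
  zcoord <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  zs_big <- aperm(array(rep(zs_mat, each = 1), c(d[2], d[3], d[1])), c(3, 1, 2))
  zg <- zcoord - zs_big
  rm(zcoord, zs_big)
  tmol_vox <- cfg$molecular_thickness_um / vl
  vol[zg >= 0 & zg < tmol_vox] <- ints$molecular
  vol[zg >= tmol_vox] <- ints$paraffin

  # cells on the sheet, dart throwing
  clear_um <- cfg$border_clear_vox * vl
  ext_y <- (d[2] - 1) * vl; ext_x <- (d[3] - 1) * vl
  n_target <- round(cfg$cell_density_per_mm2 * phantom_layer_area_mm2(cfg))
  spacing_um <- cfg$min_spacing_factor / sqrt(max(cfg$cell_density_per_mm2,
                                                  1e-12)) * 1000
  cells_um <- matrix(numeric(0), 0, 3)  # (z, y, x) um
  if (n_target > 0) {
    attempts <- 0L
    max_attempts <- 200L * n_target
    while (nrow(cells_um) < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      cx <- runif(1, clear_um, ext_x - clear_um)
      cy <- runif(1, clear_um, ext_y - clear_um)
      cz <- (phantom_surface_z_vox(cfg, cx, cy) - 1) * vl
      cand <- c(cz, cy, cx)
      if (nrow(cells_um) > 0) {
        dmin <- sqrt(min(rowSums(sweep(cells_um, 2, cand)^2)))
        if (dmin < spacing_um) next
      }
      cells_um <- rbind(cells_um, cand)
    }
    if (nrow(cells_um) < n_target)
      stop(sprintf(paste0("requested cell density infeasible: placed %d of ",
                          "%d somata"), nrow(cells_um), n_target))
  }

  # vessels: persistent random walks through the tissue (reflected off the
  # paraffin boundary), kept clear of somata
  soma_r_vox <- cfg$soma_radius_um / vl
  vessel_paths <- list()
  vessel_radii_um <- numeric(0)
  if (cfg$n_vessels > 0) {
    clearance_vox <- soma_r_vox + max(cfg$vessel_radius_um) / vl + 8
    cells_vox <- if (nrow(cells_um)) cells_um / vl + 1 else cells_um
    for (k in seq_len(cfg$n_vessels)) {
      ok <- FALSE
      for (try in 1:50) {
        r_um <- runif(1, cfg$vessel_radius_um[1], cfg$vessel_radius_um[2])
        pos <- c(runif(1, 0.2, 0.8) * d[1], runif(1, 0.2, 0.8) * d[2], 1)
        dir <- c(rnorm(2, 0, 0.2), 1)
        dir <- dir / sqrt(sum(dir^2))
        path <- matrix(pos, 1, 3)
        for (step in 1:400) {
          dir <- dir + c(rnorm(2, 0, 0.15), rnorm(1, 0, 0.15))
          dir <- dir / sqrt(sum(dir^2))
          pos <- pos + 3 * dir
          # stay out of the paraffin stratum
          zs_here <- phantom_surface_z_vox(cfg, (pos[3] - 1) * vl,
                                           (pos[2] - 1) * vl)
          if (pos[1] > zs_here + tmol_vox - 10) dir[1] <- -abs(dir[1])
          if (pos[1] < 8) dir[1] <- abs(dir[1])
          if (any(pos < 1) || any(pos > d)) break
          path <- rbind(path, pos)
        }
        if (nrow(path) < 20) next
        if (nrow(cells_um)) {
          dmin <- min(apply(cells_vox, 1, function(cc)
            sqrt(min(colSums((t(path) - cc)^2)))))
          if (dmin < clearance_vox) next
        }
        ok <- TRUE
        break
      }
      if (!ok) next  # skip this vessel; count reflects placements
      vessel_paths[[length(vessel_paths) + 1L]] <- path
      vessel_radii_um <- c(vessel_radii_um, r_um)
    }
  }

  # Corpora amylacea: off-layer bright spheres in the tissue
  corpora <- matrix(numeric(0), 0, 4)  # z, y, x (vox), radius_um
  if (cfg$n_corpora > 0) {
    tries <- 0L
    while (nrow(corpora) < cfg$n_corpora && tries < 500L * cfg$n_corpora) {
      tries <- tries + 1L
      r_um <- runif(1, cfg$corpus_radius_um[1], cfg$corpus_radius_um[2])
      r_vox <- r_um / vl
      cy <- runif(1, clear_um, ext_y - clear_um)
      cx <- runif(1, clear_um, ext_x - clear_um)
      zs_here <- phantom_surface_z_vox(cfg, cx, cy)
      side <- sample(c(-1, 1), 1)
      zlim <- if (side < 0) c(10, zs_here - 60) else
        c(zs_here + 60, zs_here + tmol_vox - 4)
      if (zlim[2] <= zlim[1]) next
      cz <- runif(1, zlim[1], zlim[2])
      if (cz < r_vox + 2 || cz > d[1] - r_vox - 2) next
      cand_vox <- c(cz, cy / vl + 1, cx / vl + 1)
      if (nrow(corpora) &&
          sqrt(min(rowSums(sweep(corpora[, 1:3, drop = FALSE], 2,
                                 cand_vox)^2))) < 10) next
      corpora <- rbind(corpora, c(cand_vox, r_um))
    }
  }

  # background gradients: random linear drift + radial cupping in (y, x)
  bg <- cfg$background
  if (bg$linear > 0) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    zn <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1) - 0.5
    yn <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 0.5
    xn <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1) - 0.5
    vol <- vol + bg$linear * (rep(zn * u[1], times = d[2] * d[3]) +
                                rep(rep(yn * u[2], each = d[1]), times = d[3]) +
                                rep(xn * u[3], each = d[1] * d[2]))
  }
  if (bg$radial > 0) {
    cy0 <- (d[2] + 1) / 2; cx0 <- (d[3] + 1) / 2
    rr <- outer((seq_len(d[2]) - cy0)^2, (seq_len(d[3]) - cx0)^2, "+")
    rr <- rr / max(rr)
    vol <- vol + bg$radial * rep(as.vector(rr - 0.5), each = d[1])
  }

  # render vessels, corpora, somata, nucleoli (brightest last)
  for (k in seq_along(vessel_paths)) {
    path <- vessel_paths[[k]]
    r_vox <- vessel_radii_um[k] / vl
    # densify the polyline to 1-voxel steps and stamp spheres
    for (seg in seq_len(nrow(path) - 1)) {
      a <- path[seg, ]; b <- path[seg + 1, ]
      len <- sqrt(sum((b - a)^2))
      for (t in seq(0, 1, by = 1 / max(2, ceiling(len)))) {
        vol <- stamp_sphere(vol, a + t * (b - a), r_vox, cfg$soma_intensity)
      }
    }
  }
  if (nrow(corpora)) {
    for (k in seq_len(nrow(corpora)))
      vol <- stamp_sphere(vol, corpora[k, 1:3], corpora[k, 4] / vl,
                          cfg$corpus_intensity)
  }
  cells_vox <- if (nrow(cells_um)) cells_um / vl + 1 else
    matrix(numeric(0), 0, 3)
  if (nrow(cells_vox)) {
    for (k in seq_len(nrow(cells_vox))) {
      vol <- stamp_sphere(vol, cells_vox[k, ], soma_r_vox,
                          cfg$soma_intensity)
      vol <- stamp_sphere(vol, cells_vox[k, ], cfg$nucleolus_radius_um / vl,
                          cfg$nucleolus_intensity)
    }
  }

  # Gaussian noise calibrated to the molecular-paraffin contrast
  sigma <- abs(ints$molecular - ints$paraffin) / cfg$target_snr
  vol <- vol + array(rnorm(prod(d), 0, sigma), d)

  truth_rows <- list()
  if (nrow(cells_vox)) {
    truth_rows$cells <- data.frame(
      class = "cell",
      z = round(cells_vox[, 1], 3), y = round(cells_vox[, 2], 3),
      x = round(cells_vox[, 3], 3),
      param1 = round(cfg$soma_radius_um, 4), param2 = NA_real_,
      nucleolus_z = round(cells_vox[, 1], 3),
      nucleolus_y = round(cells_vox[, 2], 3),
      nucleolus_x = round(cells_vox[, 3], 3))
  }
  if (length(vessel_paths)) {
    vp <- t(vapply(vessel_paths, colMeans, numeric(3)))
    vlens <- vapply(vessel_paths, function(pp)
      sum(sqrt(rowSums(diff(pp)^2))) * vl, numeric(1))
    truth_rows$vessels <- data.frame(
      class = "vessel", z = round(vp[, 1], 3), y = round(vp[, 2], 3),
      x = round(vp[, 3], 3), param1 = round(vessel_radii_um, 4),
      param2 = round(vlens, 3), nucleolus_z = NA_real_,
      nucleolus_y = NA_real_, nucleolus_x = NA_real_)
  }
  if (nrow(corpora)) {
    truth_rows$corpora <- data.frame(
      class = "corpus", z = round(corpora[, 1], 3),
      y = round(corpora[, 2], 3), x = round(corpora[, 3], 3),
      param1 = round(corpora[, 4], 4), param2 = NA_real_,
      nucleolus_z = NA_real_, nucleolus_y = NA_real_,
      nucleolus_x = NA_real_)
  }
  truth <- if (length(truth_rows)) do.call(rbind, c(truth_rows,
                                                    make.row.names = FALSE))
  else data.frame(class = character(), z = numeric(), y = numeric(),
                  x = numeric(), param1 = numeric(), param2 = numeric(),
                  nucleolus_z = numeric(), nucleolus_y = numeric(),
                  nucleolus_x = numeric())
  class(truth) <- c("phantom_truth", "data.frame")

  volume <- volume3d(vol, vl,
                     provenance = sprintf("synthetic phantom (seed %d)",
                                          cfg$rng_seed))
  list(volume = volume, truth = truth)
}

#' Write / read a phantom ground-truth table as CSV
#'
#' Plain CSV with header
#' `class,z,y,x,param1,param2,nucleolus_z,nucleolus_y,nucleolus_x`;
#' round-trips losslessly.
#'
#' @param truth A `phantom_truth` data.frame.
#' @param path CSV path.
#' @return `path` (writer) / the truth table (reader).
#' @export
truth_to_csv <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_to_csv
#' @export
truth_from_csv <- function(path) {
  truth <- read.csv(path, colClasses = c(class = "character"))
  class(truth) <- c("phantom_truth", "data.frame")
  truth
}

#' Single-cell fixture with a dendritic tree
#'
#' A small sub-micron-voxel volume holding one soma with an attached
#' branching tube tree (trunk plus two branches), and optionally a second,
#' smaller disjoint tree; used to exercise the dendrite segmentation mode.
#'
#' @param shape Volume shape (default 96^3).
#' @param voxel_len_um Voxel length (default 0.45 um).
#' @param include_second_tree Add a disjoint smaller tree.
#' @param rng_seed Seed for the noise.
#' @return A list with `volume` and `truth` (list of tree voxel extents).
#' @export
phantom_dendrite_cell <- function(shape = c(96, 96, 96), voxel_len_um = 0.45,
                                  include_second_tree = TRUE, rng_seed = 7) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(rng_seed)
  d <- as.integer(shape)
  vol <- array(0.4, d)
  soma_c <- c(0.72, 0.5, 0.5) * d
  stamp_tube <- function(vol, a, b, r) {
    len <- sqrt(sum((b - a)^2))
    for (t in seq(0, 1, by = 1 / max(2, ceiling(len))))
      vol <- stamp_sphere(vol, a + t * (b - a), r, 0.62)
    vol
  }
  vol <- stamp_sphere(vol, soma_c, 9, 0.62)
  trunk_top <- soma_c - c(26, 0, 0)
  vol <- stamp_tube(vol, soma_c - c(7, 0, 0), trunk_top, 2)
  vol <- stamp_tube(vol, trunk_top, trunk_top + c(-18, 12, 9), 1.7)
  vol <- stamp_tube(vol, trunk_top, trunk_top + c(-18, -11, -8), 1.7)
  if (include_second_tree) {
    base2 <- c(0.8, 0.15, 0.82) * d
    vol <- stamp_tube(vol, base2, base2 + c(-14, 4, -4), 1.6)
  }
  vol <- vol + array(rnorm(prod(d), 0, 0.01), d)
  list(volume = volume3d(vol, voxel_len_um, provenance = "dendrite fixture"),
       truth = list(soma_centre_vox = soma_c))
}
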