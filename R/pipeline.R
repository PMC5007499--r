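#' Default pipeline configuration
#'
#' Nested configuration mirroring every stage's parameter set, with the
#' published values as defaults wherever the study states one. Sections:
#' `phantom`, `normalise`, `cell_mode`, `dendrite_mode`, `segmentation`,
#' `refinement`, `layer`, `evaluation`, plus the run `seed` (which also
#' seeds the phantom generator). Unknown keys are rejected on merge so
#' typos cannot silently fall back to defaults.
#'
#' @param ... Named overrides; nested sections are merged recursively
#'   (e.g. `segmentation = list(response_threshold = 0.1)`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 42L,
    phantom = unclass(phantom_config()),
    normalise = list(lo_pct = 0.1, hi_pct = 99.9),
    cell_mode = unclass(cell_mode_params()),
    dendrite_mode = unclass(dendrite_mode_params()),
    segmentation = unclass(segmentation_params()),
    refinement = unclass(refinement_params()),
    layer = unclass(layer_params()),
    evaluation = list(match_radius_um = 10)
  )
  cfg <- merge_config(defaults, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", path, nm)
    dv <- defaults[[nm]]; uv <- user[[nm]]
    if (is.list(dv) && !is.null(names(dv)) && is.list(uv)) {
      defaults[[nm]] <- merge_config(dv, uv, paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- uv
    }
  }
  defaults
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the [pipeline_config()] structure; loading merges the
#' file over the defaults and rejects unknown keys, so a dumped
#' configuration round-trips to the in-memory one.
#'
#' @param path YAML file path.
#' @param cfg A `pipeline_config`.
#' @return The configuration (reader) / `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(pipeline_config, user)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_section <- function(cfg, name, constructor) {
  do.call(constructor, cfg[[name]])
}

#' Signal-to-noise ROI pair for a phantom scene
#'
#' Places a cubic region in the molecular stratum (24 voxels above the
#' layer sheet at the lateral centre, clear of the somata) and one in the
#' paraffin background above the tissue, each `size^3 >= 600` voxels, for
#' use with [snr()].
#'
#' @param cfg A [phantom_config()] (or the `phantom` section of a pipeline
#'   config as a list).
#' @param size Cube edge in voxels (default 9, i.e. 729 voxels).
#' @return A list with `mol` and `par` [roi_box()]es.
#' @export
phantom_snr_rois <- function(cfg, size = 9) {
  if (!inherits(cfg, "phantom_config")) cfg <- do.call(phantom_config, cfg)
  d <- cfg$shape
  vl <- cfg$voxel_len_um
  cx_um <- (d[3] - 1) / 2 * vl
  cy_um <- (d[2] - 1) / 2 * vl
  zs <- phantom_surface_z_vox(cfg, cx_um, cy_um)
  tmol_vox <- cfg$molecular_thickness_um / vl
  half <- floor(size / 2)
  lat0 <- c(round(d[2] / 2) - half - 1L, round(d[3] / 2) - half - 1L)
  z_mol <- round(zs + 24) - half - 1L
  z_par <- round(zs + tmol_vox + 15)
  z_par <- min(z_par, d[1] - size)  # stay inside
  mol <- roi_box(c(z_mol, lat0[1], lat0[2]), rep(size, 3))
  par <- roi_box(c(z_par, lat0[1], lat0[2]), rep(size, 3))
  list(mol = mol, par = par)
}

#' Run the detection pipeline
#'
#' Chains the stages: phantom generation (or an input volume), intensity
#' normalisation, cell-mode Frangi filtering, object extraction and
#' geometric classification, cell refinement with nucleolus segmentation,
#' layer-population selection with manifold extraction and local density,
#' and evaluation against ground truth plus SNR and the scan budget. Each
#' stage's result is returned; when `out_dir` is given the artifacts
#' (volume, truth/object/cell tables, surface PLY, summary and report
#' JSON, run manifest) are written there.
#'
#' @param config A [pipeline_config()].
#' @param stage One of `"phantom"`, `"detect"`, `"refine"`, `"layer"`,
#'   `"evaluate"`, `"snr"`, `"plan"`, `"all"`; prerequisite stages are run
#'   automatically.
#' @param out_dir Optional output directory (created if missing).
#' @param volume Optional input [volume3d] (otherwise the phantom is
#'   generated).
#' @param truth Optional ground-truth table for evaluation.
#' @param verbose Print per-stage progress.
#' @return A list of stage results (invisible), including `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), stage = "all",
                         out_dir = NULL, volume = NULL, truth = NULL,
                         verbose = TRUE) {
  stage <- match.arg(stage, c("phantom", "detect", "refine", "layer",
                              "evaluate", "snr", "plan", "all"))
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  res <- list()
  artifacts <- character()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
  }

  pcfg <- do.call(phantom_config,
                  modifyList(config$phantom, list(rng_seed = config$seed)))
  needs_volume <- stage %in% c("detect", "refine", "layer", "evaluate",
                               "snr", "all")
  needs_phantom <- stage %in% c("phantom", "all") ||
    (needs_volume && is.null(volume))

  if (needs_phantom) {
    say("[phantom] generating %s phantom (seed %d)",
        paste(pcfg$shape, collapse = "x"), pcfg$rng_seed)
    ph <- phantom_generate(pcfg)
    volume <- ph$volume
    if (is.null(truth)) truth <- ph$truth
    res$truth <- truth
    emit("phantom.nrrd", function(p) write_volume(volume, p))
    emit("truth.csv", function(p) truth_to_csv(truth, p))
  }
  res$volume <- volume

  needs_detect <- stage %in% c("detect", "refine", "layer", "evaluate",
                               "snr", "all")
  if (needs_detect) {
    say("[detect] normalising and filtering (scales %s)",
        paste(config$cell_mode$scales_vox, collapse = ","))
    vn <- normalise_volume(volume, config$normalise$lo_pct,
                           config$normalise$hi_pct)
    resp <- frangi_response(vn, config_section(config, "cell_mode",
                                               frangi_params))
    sp <- config_section(config, "segmentation", segmentation_params)
    objs <- classify_objects(extract_objects(resp, sp), sp)
    res$normalised <- vn
    res$objects <- objs
    res$object_table <- object_table(objs)
    tab <- res$object_table
    say("[detect] %d objects: %s", nrow(tab),
        paste(sprintf("%s=%d", names(table(tab$cls)), table(tab$cls)),
              collapse = ", "))
    emit("objects.csv", function(p) write.csv(tab, p, row.names = FALSE))
    rm(resp)
  }

  if (stage %in% c("refine", "all")) {
    say("[refine] region growing + nucleolus segmentation")
    rp <- config_section(config, "refinement", refinement_params)
    res$cells <- refine_cells(res$normalised, res$objects, rp)
    emit("cells.csv", function(p) write.csv(res$cells, p, row.names = FALSE))
  }

  lp <- config_section(config, "layer", layer_params)
  if (stage %in% c("layer", "evaluate", "all")) {
    cand <- res$object_table[res$object_table$cls == "cell_candidate", ]
    centroids <- cbind(z = cand$centroid_z, y = cand$centroid_y,
                       x = cand$centroid_x)
    say("[layer] selecting layer population from %d candidates",
        nrow(centroids))
    kept <- select_layer_population(centroids, lp, dim(volume))
    res$layer_centroids <- kept
    if (nrow(kept) >= 4) {
      surf <- extract_layer_surface(kept, lp, dim(volume),
                                    volume$voxel_len_um)
      vols <- if (!is.null(res$cells)) res$cells$volume_um3 else NULL
      surf <- local_density(surf, kept, lp, cell_volumes_um3 = vols)
      res$surface <- surf
      say("[layer] area %.3g mm^2, mean local density %.1f /mm^2",
          surf$area_mm2, surf$summary$mean_density_per_mm2)
      emit("surface.ply", function(p) write_ply(surf, p))
      emit("layer_summary.json", function(p)
        jsonlite::write_json(surf$summary, p, auto_unbox = TRUE, digits = NA))
    } else {
      say("[layer] too few cells in the layer population; surface skipped")
    }
  }

  if (stage %in% c("evaluate", "all")) {
    if (is.null(truth)) stop("evaluation requires a ground-truth table")
    vl <- volume$voxel_len_um
    tc <- truth[truth$class == "cell", c("z", "y", "x")]
    det_um <- (res$layer_centroids - 1) * vl
    truth_um <- (as.matrix(tc) - 1) * vl
    rep_ <- detection_error(det_um, truth_um,
                            config$evaluation$match_radius_um)
    res$report <- rep_
    say("[evaluate] TP %d FP %d FN %d -> error %.2f%%",
        rep_$true_positives, rep_$false_positives, rep_$false_negatives,
        rep_$error_pct)
    emit("detection_report.json", function(p)
      jsonlite::write_json(unclass(rep_), p, auto_unbox = TRUE, digits = NA))
  }

  if (stage %in% c("snr", "all")) {
    rois <- phantom_snr_rois(pcfg)
    res$snr <- snr(volume, rois$mol, rois$par)
    say("[snr] measured SNR %.2f (target %.2f)", res$snr, pcfg$target_snr)
    emit("snr.json", function(p)
      jsonlite::write_json(list(snr = res$snr, target = pcfg$target_snr),
                           p, auto_unbox = TRUE, digits = NA))
  }

  if (stage %in% c("plan", "all")) {
    res$plan <- scan_plan()
    emit("scan_plan.json", function(p)
      jsonlite::write_json(unclass(res$plan), p, auto_unbox = TRUE,
                           digits = NA))
  }

  res$manifest <- list(
    package = "purkinje3d",
    version = as.character(packageVersion("purkinje3d")),
    stage = stage,
    seed = config$seed,
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    artifacts = artifacts,
    config = unclass(config))
  emit("manifest.json", function(p)
    jsonlite::write_json(res$manifest, p, auto_unbox = TRUE, digits = NA))
  invisible(res)
}
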