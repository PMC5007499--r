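#' Detection-error report from detected and ground-truth positions
#'
#' Detections and truths are matched greedily under `match_radius_um`: all
#' candidate pairs within the radius are sorted by distance and consumed
#' nearest-first, each point used at most once. Unmatched detections are
#' false positives, unmatched truths false negatives, and the localisation
#' error is \eqn{100 (FP + FN) / n_{detected}} -- the denominator is the
#' number of detections, reproducing the published arithmetic
#' ((3 + 2) / 108 rounds to 5 percent).
#'
#' @param detected N x 3 matrix of detected positions (um).
#' @param truth M x 3 matrix of ground-truth positions (um).
#' @param match_radius_um Matching radius (um), > 0 (default 10).
#' @return An object of class `detection_report`: `n_detected`, `n_truth`,
#'   `true_positives`, `false_positives`, `false_negatives`, `error_pct`
#'   (two decimals; `Inf` when nothing was detected but truths exist),
#'   `error_pct_rounded` (integer) and `match_radius_um`.
#' @export
detection_error <- function(detected, truth, match_radius_um = 10) {
  if (match_radius_um <= 0) stop("`match_radius_um` must be > 0")
  detected <- matrix(as.numeric(detected), ncol = 3)
  truth <- matrix(as.numeric(truth), ncol = 3)
  nd <- nrow(detected); nt <- nrow(truth)
  tp <- 0L
  if (nd > 0 && nt > 0) {
    d2 <- outer(rowSums(detected^2), rep(1, nt)) -
      2 * detected %*% t(truth) + outer(rep(1, nd), rowSums(truth^2))
    d2[d2 < 0] <- 0
    cand <- which(d2 <= match_radius_um^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d2[cand])
      used_d <- logical(nd); used_t <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE; used_t[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  detection_report(n_detected = nd, false_positives = nd - tp,
                   false_negatives = nt - tp,
                   match_radius_um = match_radius_um)
}

#' Detection-error report from counts
#'
#' Builds the report directly from the counts (e.g. the published 108
#' detections with 3 false positives and 2 false negatives).
#'
#' @param n_detected Number of detections.
#' @param false_positives,false_negatives Error counts.
#' @param match_radius_um Matching radius recorded in the report.
#' @return A `detection_report`; see [detection_error()].
#' @export
detection_report <- function(n_detected, false_positives, false_negatives,
                             match_radius_um = NA_real_) {
  tp <- n_detected - false_positives
  if (tp < 0) stop("`false_positives` cannot exceed `n_detected`")
  err <- if (n_detected == 0) {
    if (false_negatives > 0) Inf else 0
  } else 100 * (false_positives + false_negatives) / n_detected
  structure(list(n_detected = as.integer(n_detected),
                 n_truth = as.integer(tp + false_negatives),
                 true_positives = as.integer(tp),
                 false_positives = as.integer(false_positives),
                 false_negatives = as.integer(false_negatives),
                 error_pct = round(err, 2),
                 error_pct_rounded = if (is.finite(err)) as.integer(round(err))
                 else NA_integer_,
                 match_radius_um = match_radius_um),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %d detected / %d truth | TP %d, FP %d, FN %d\n",
              x$n_detected, x$n_truth, x$true_positives, x$false_positives,
              x$false_negatives))
  cat(sprintf("  localisation error (FP+FN)/n_detected: %.2f%% (~%s%%)\n",
              x$error_pct,
              ifelse(is.na(x$error_pct_rounded), "NA",
                     x$error_pct_rounded)))
  invisible(x)
}

#' Signal-to-noise ratio between a tissue and a background region
#'
#' \eqn{SNR = |\bar x_{mol} - \bar x_{par}| / \sigma_{par}}, where the
#' first region samples the Stratum moleculare and the second the paraffin
#' background; both regions must hold at least 600 voxels. Invariant under
#' affine rescaling of the intensities.
#'
#' @param v A [volume3d].
#' @param mol_roi,par_roi [roi_box()]es for the tissue and background
#'   regions.
#' @param min_region_vox Minimal region size in voxels (default 600).
#' @return The SNR (a single number).
#' @export
snr <- function(v, mol_roi, par_roi, min_region_vox = 600) {
  stop_if_not_volume(v)
  mol <- crop_volume(v, mol_roi)$data
  par <- crop_volume(v, par_roi)$data
  if (length(mol) < min_region_vox || length(par) < min_region_vox)
    stop("both regions must hold at least ", min_region_vox, " voxels")
  s <- sd(par)
  if (s == 0) stop("degenerate background region: zero standard deviation")
  abs(mean(mol) - mean(par)) / s
}

#' Whole-organ scan-budget calculator
#'
#' Number of tomographic scans and total beam time needed to cover a whole
#' cerebellum at the working resolution:
#' `n_scans = ceiling(brain_volume_mm3 * cerebellum_fraction /
#' scan_volume_mm3)` and `total_days = ceiling(n_scans * scan_time_min /
#' 1440)`. With the defaults (1.3 dm^3 brain, 10 percent cerebellum,
#' 20 mm^3 per scan, 5 min per scan) this yields 6,500 scans and 23 days.
#'
#' @param brain_volume_mm3 Whole-brain volume (default 1.3e6 mm^3).
#' @param cerebellum_fraction Cerebellar fraction of the brain volume.
#' @param scan_volume_mm3 Volume covered by a single scan.
#' @param scan_time_min Scan time in minutes.
#' @return An object of class `scan_plan` with the inputs plus `n_scans`
#'   and `total_days`.
#' @export
scan_plan <- function(brain_volume_mm3 = 1.3e6, cerebellum_fraction = 0.10,
                      scan_volume_mm3 = 20, scan_time_min = 5) {
  vals <- c(brain_volume_mm3, cerebellum_fraction, scan_volume_mm3,
            scan_time_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all scan-plan inputs must be positive")
  n_scans <- max(1L, as.integer(ceiling(brain_volume_mm3 *
                                          cerebellum_fraction /
                                          scan_volume_mm3)))
  total_days <- as.integer(ceiling(n_scans * scan_time_min / 1440))
  structure(list(brain_volume_mm3 = brain_volume_mm3,
                 cerebellum_fraction = cerebellum_fraction,
                 scan_volume_mm3 = scan_volume_mm3,
                 scan_time_min = scan_time_min,
                 n_scans = n_scans, total_days = total_days),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan> %.3g mm^3 brain x %.0f%% cerebellum / %.3g mm^3 per scan\n",
              x$brain_volume_mm3, 100 * x$cerebellum_fraction,
              x$scan_volume_mm3))
  cat(sprintf("  -> %d scans x %.3g min = %d day(s) of beam time\n",
              x$n_scans, x$scan_time_min, x$total_days))
  invisible(x)
}
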