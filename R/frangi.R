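#' Parameters of the multi-scale Frangi vesselness filter
#'
#' The filter classifies local second-order structure from the eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2| \le |\lambda_3|} of the scale-normalised
#' 3D Hessian. Its three sensitivities weight the plate-vs-tube ratio
#' \eqn{R_a = |\lambda_2|/|\lambda_3|}, the blobness ratio
#' \eqn{R_b = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}} and the second-order
#' structuredness \eqn{S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}.
#'
#' `gamma` is only meaningful relative to the intensity scale the Hessian is
#' computed on: on a `[0,1]`-normalised volume `S` is of order 0.1, so with
#' the published sensitivities (cell mode `gamma = 40`) the structuredness
#' term would suppress everything. `intensity_scale` is therefore applied to
#' the intensities before the Hessian. Its default (240) places the
#' structuredness of soma-scale structures at the working contrast
#' (about 0.2 after normalisation) in the filter's discriminating range
#' `S` of roughly 1-2 `gamma`: large enough that genuine structure passes
#' the S-term, small enough that the term still truncates the response halo
#' around bright blobs and suppresses noise, which keeps the detected
#' components at soma size (the published 300-3000 voxel gate presumes
#' exactly that).
#'
#' @param alpha Sensitivity of the plate/tube ratio `R_a` (> 0).
#' @param beta Sensitivity of the blobness ratio `R_b` (> 0).
#' @param gamma Sensitivity of the structuredness `S` (> 0).
#' @param scales_vox Integer vector of Gaussian scales in voxels (all >= 1);
#'   the filter response is the maximum over these scales.
#' @param polarity `"bright"` for bright structures on a dark background
#'   (the pipeline default), `"dark"` for the mirrored sign condition.
#' @param intensity_scale Multiplier applied to intensities before the
#'   Hessian (> 0); see Details.
#' @return An object of class `frangi_params`.
#' @seealso [cell_mode_params()], [dendrite_mode_params()], [frangi_response()]
#' @export
frangi_params <- function(alpha, beta, gamma, scales_vox,
                          polarity = c("bright", "dark"),
                          intensity_scale = 240) {
  polarity <- match.arg(polarity)
  if (any(c(alpha, beta, gamma, intensity_scale) <= 0))
    stop("`alpha`, `beta`, `gamma` and `intensity_scale` must be > 0")
  scales_vox <- as.integer(scales_vox)
  if (length(scales_vox) == 0L || any(scales_vox < 1L))
    stop("`scales_vox` must be a non-empty set of integer scales >= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 scales_vox = sort(unique(scales_vox)), polarity = polarity,
                 intensity_scale = intensity_scale),
            class = "frangi_params")
}

#' Cell-mode Frangi parameters
#'
#' Soma detection mode: scales 3 to 6 voxels (5.25 to 10.5 um at 1.75 um
#' voxels), `alpha = 0.2`, `beta = 0.5`, `gamma = 40`.
#' @param ... Overrides passed to [frangi_params()].
#' @return A `frangi_params` object.
#' @export
cell_mode_params <- function(...) {
  defaults <- list(alpha = 0.2, beta = 0.5, gamma = 40, scales_vox = 3:6,
                   polarity = "bright", intensity_scale = 240)
  do.call(frangi_params, modifyList(defaults, list(...)))
}

#' Dendrite-mode Frangi parameters
#'
#' Dendritic-tree mode for sub-micron volumes: scales 1 to 3 voxels,
#' `alpha = 0.5`, `beta = 0.1`, `gamma = 10`.
#' @param ... Overrides passed to [frangi_params()].
#' @return A `frangi_params` object.
#' @export
dendrite_mode_params <- function(...) {
  defaults <- list(alpha = 0.5, beta = 0.1, gamma = 10, scales_vox = 1:3,
                   polarity = "bright", intensity_scale = 240)
  do.call(frangi_params, modifyList(defaults, list(...)))
}

#' Eigenvalues of the scale-normalised 3D Hessian
#'
#' The Hessian is computed by Gaussian-derivative convolution at standard
#' deviation `s` voxels (kernel truncated at 4 sigma, reflected boundaries)
#' and multiplied by `s^2` (gamma-normalisation), so responses are
#' comparable across scales. Eigenvalues are sorted per voxel by absolute
#' value, `|e1| <= |e2| <= |e3|`.
#'
#' @param v A [volume3d].
#' @param s Scale in voxels (>= 1); the volume must be larger than the
#'   truncated kernel support along every axis.
#' @return An object of class `hessian_eigs`: list of three arrays `e1`,
#'   `e2`, `e3` plus the `scale`.
#' @export
hessian_eigenvalues <- function(v, s) {
  stop_if_not_volume(v)
  if (s < 1) stop("scale `s` must be >= 1 voxel")
  d <- dim(v$data)
  r <- max(1, ceiling(4 * s))
  if (any(d < r + 1))
    stop(sprintf(paste0("volume (%s) smaller than the kernel support ",
                        "(radius %d voxels at scale %g)"),
                 paste(d, collapse = "x"), r, s))
  e <- .cpp_hessian_eigs(as.vector(v$data), d, as.numeric(s))
  for (k in 1:3) dim(e[[k]]) <- d
  structure(list(e1 = e$e1, e2 = e$e2, e3 = e$e3, scale = s),
            class = "hessian_eigs")
}

#' Scalar Frangi vesselness measure from Hessian eigenvalues
#'
#' Evaluates, element-wise, \deqn{V = (1 - e^{-R_a^2/2\alpha^2}) \,
#' e^{-R_b^2/2\beta^2} \, (1 - e^{-S^2/2\gamma^2})}{V = (1 - exp(-Ra^2/2a^2))
#' exp(-Rb^2/2b^2) (1 - exp(-S^2/2g^2))} with `V = 0` wherever the polarity
#' sign condition fails (bright: `e2 > 0` or `e3 > 0`; dark: mirrored) or
#' the local structure is degenerate (`e3 = 0`). Exposed separately so the
#' formula can be checked against scalar hand evaluation independently of
#' the volumetric code path.
#'
#' @param e1,e2,e3 Eigenvalues sorted by absolute value (vectors or arrays).
#' @param p A [frangi_params()] object; `intensity_scale` is *not* applied
#'   here (the caller controls the intensity scale of the eigenvalues).
#' @return The vesselness measure, in `[0, 1]`, same shape as the input.
#' @export
frangi_measure <- function(e1, e2, e3, p) {
  a2 <- abs(e2); a3 <- abs(e3)
  # degenerate voxels (a3 == 0, or a2 == 0 with 0/0) yield NaN here and are
  # zeroed below; avoids per-element branching on large arrays
  Ra2 <- (a2 / a3)^2
  Rb2 <- (e1 * e1) / (a2 * a3)
  S2 <- e1^2 + e2^2 + e3^2
  V <- (1 - exp(-Ra2 / (2 * p$alpha^2))) *
    exp(-Rb2 / (2 * p$beta^2)) *
    (1 - exp(-S2 / (2 * p$gamma^2)))
  bad <- if (p$polarity == "bright") (e2 > 0) | (e3 > 0) else
    (e2 < 0) | (e3 < 0)
  V[bad] <- 0
  V[!is.finite(V)] <- 0
  V
}

#' Multi-scale Frangi vesselness response
#'
#' Per voxel, the vesselness measure is evaluated at every scale in
#' `p$scales_vox` on the `intensity_scale`-scaled, gamma-normalised Hessian
#' eigenvalues; the response is the maximum over scales and lies in
#' `[0, 1]`.
#'
#' @param v A [volume3d].
#' @param p A [frangi_params()] object.
#' @return A [volume3d] holding the response.
#' @export
frangi_response <- function(v, p) {
  stop_if_not_volume(v)
  if (!inherits(p, "frangi_params")) stop("`p` must be frangi_params")
  resp <- NULL
  for (s in p$scales_vox) {
    e <- hessian_eigenvalues(v, s)
    k <- p$intensity_scale
    Vs <- frangi_measure(k * e$e1, k * e$e2, k * e$e3, p)
    resp <- if (is.null(resp)) Vs else pmax(resp, Vs)
    rm(e, Vs)
  }
  dim(resp) <- dim(v$data)
  volume3d(resp, v$voxel_len_um,
           provenance = c(v$provenance,
                          sprintf("frangi response (scales %s, %s)",
                                  paste(p$scales_vox, collapse = ","),
                                  p$polarity)))
}

#' Gaussian smoothing of a 3D array
#'
#' Separable Gaussian filter (kernel truncated at 4 sigma, reflected
#' boundaries); used for smoothing coarse distance grids and available as a
#' general utility.
#'
#' @param a 3D numeric array.
#' @param sigma Standard deviation in array-index units (> 0).
#' @return The smoothed array, same shape.
#' @export
gauss_smooth3d <- function(a, sigma) {
  if (!is.array(a) || length(dim(a)) != 3L) stop("`a` must be a 3D array")
  if (sigma <= 0) stop("`sigma` must be > 0")
  out <- .cpp_gauss_filter3d(as.vector(a), dim(a), as.numeric(sigma),
                             c(0L, 0L, 0L))
  dim(out) <- dim(a)
  out
}
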