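---
title: "Label-free Purkinje-cell detection in phase tomograms: models and methods"
author: "purkinje3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free Purkinje-cell detection in phase tomograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hard X-ray phase-contrast tomography of paraffin-embedded cerebellum
resolves individual Purkinje cells — and even their nucleoli — in three
dimensions without any staining. The cells form a one-cell-thick folded
sheet between the molecular and granular strata, so counting them and
measuring their *surface* density (cells per mm² of layer) is far more
robust than a volumetric density, which depends strongly on how much
empty volume the region of interest happens to include. `purkinje3d`
implements the full post-reconstruction pipeline: from a raw 3D scalar
volume to classified objects, refined cell masks with nucleoli, an
extracted layer manifold with local densities, and the accompanying
error, signal-to-noise and scan-budget accounting. A synthetic phantom
generator with exact ground truth makes the whole chain testable at desk
scale.

## Pipeline overview

1. **Normalisation** (`normalise_volume`): intensities are clipped to the
   0.1–99.9 percentiles and rescaled to [0, 1]. This step is mandatory
   because a downstream parameter — the region-growing intensity distance
   of 0.0385 — is an *absolute* tolerance that is only meaningful on a
   fixed scale.
2. **Multi-scale vesselness** (`frangi_response`): per voxel, the
   eigenvalues $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$ of the
   Gaussian-scale Hessian give the ratios
   $R_a = |\lambda_2|/|\lambda_3|$ (plate vs. tube),
   $R_b = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ (blobness) and the
   structuredness $S = \lVert\lambda\rVert_2$, combined as
   $$V_s = \left(1 - e^{-R_a^2/2\alpha^2}\right)\,
           e^{-R_b^2/2\beta^2}\,
           \left(1 - e^{-S^2/2\gamma^2}\right),$$
   zero wherever the bright-polarity sign condition
   ($\lambda_2,\lambda_3 < 0$) fails; the response is the maximum over an
   integer scale range. Cell mode uses scales 3–6 voxels with
   $\alpha=0.2,\ \beta=0.5,\ \gamma=40$; dendrite mode uses scales 1–3
   voxels with $\alpha=0.5,\ \beta=0.1,\ \gamma=10$.
3. **Object extraction and geometric sorting** (`extract_objects`,
   `classify_objects`): the response is binarised, internal cavities are
   filled, 26-connected components are labelled, objects smaller than 300
   or larger than 3000 voxels and objects within 10 voxels of a dataset
   face are discarded. Each surviving object is embedded in its signed
   Euclidean distance transform; the mean level-set value over the object
   (in voxels, negative inside) summarises compactness. Objects with
   $|\overline{\phi}| > 12$ are Corpora amylacea (spheres), objects with
   $\mathrm{size}/\overline{\phi}^2 > 450$ are blood vessels (tubes), the
   remainder are Purkinje-cell candidates.
4. **Refinement** (`region_grow`, `segment_nucleolus`): each candidate is
   extended by region growing (26-connected, intensity within 0.0385 of
   the seed's initial mean, growth capped at 5 voxels from the seed) and
   the nucleolus is found at the intensity maximum inside the cell, then
   segmented by Otsu's threshold on the in-mask histogram.
5. **Layer manifold and density** (`select_layer_population`,
   `extract_layer_surface`, `local_density`): detected objects are sorted
   into a 50-voxel grid and only the largest 6-connected set of filled
   cubes is kept, which strips scattered mis-detections away from the
   layer. Distances to the remaining cells are evaluated on a 10-voxel
   coarse grid, Gaussian-smoothed (σ = 2 nodes), and the zero level of
   (distance − 44 voxels) is triangulated by marching tetrahedra into a
   closed offset surface around the cell sheet. Local density counts
   cells in a 100 µm neighbourhood per π·(100 µm)² disc.
6. **Evaluation** (`detection_error`, `snr`, `scan_plan`): greedy
   nearest-pair matching under a 10 µm radius; the localisation error is
   $100\,(FP+FN)/n_{\text{detected}}$. The SNR is
   $|\bar x_{mol}-\bar x_{par}|/\sigma_{par}$ over ≥600-voxel regions.
   The scan budget for a whole cerebellum is a ceiling division of the
   target volume by the per-scan volume times the per-scan time.

## Numerical and design choices

**Scale normalisation of the Hessian.** The Hessian at scale $s$ is
multiplied by $s^2$ (γ-normalisation). Without it, the multi-scale
maximum is always attained at the smallest scale and the published scale
ranges would be inert; with it, the per-scale response of a tube of
radius $t$ peaks at $s \approx t$ (the scale-selection property verified
in the test suite).

**The structuredness scale (`intensity_scale`).** The sensitivity γ has
the units of the Hessian, i.e. of intensity: γ = 40 cannot act on a
[0, 1]-normalised volume, where $S \sim 0.1$. The filter therefore
evaluates the Hessian on the normalised volume multiplied by
`intensity_scale` (default 240). The default was calibrated so that
soma-scale structures at the pipeline's working contrast (≈ 0.2 after
normalisation) have $S$ of about one to two γ. This range matters in both
directions: if $S \ll \gamma$ nothing responds, while if $S \gg \gamma$
the S-term saturates and stops suppressing the *halo* of the vesselness
measure — outside a bright ball the smoothed field has two negative
tangential curvatures and a small radial one, which is exactly the
signature of an ideal tube, so an unchecked response forms a saturated
shell reaching ≈ R + s from the centre. Keeping γ in its discriminating
range truncates that halo, and the detected components then match the
soma itself — which is what the published 300–3000-voxel size gate
presumes (a 10.5 µm soma is ≈ 905 voxels at 1.75 µm).

**Response threshold.** The binarisation threshold of the response is not
part of the published parameter set ("chosen by visual inspection"). The
default is 0.1: together with the calibrated `intensity_scale` it
produces components of 500–1000 voxels for planted 905-voxel somata.
Because the response dips at a blob's centre (there $R_b \approx 1$ and
the blob penalty $e^{-R_b^2/2\beta^2}$ bites) while the shell saturates,
components are binarised hollow; enclosed cavities are filled before
labelling (`fill_holes3d`).

**Level-set descriptors.** The level-set embedding is a plain signed
exact Euclidean distance transform in voxel units, and the mean over the
object's voxels is the descriptor. For continuum shapes,
$|\overline{\phi}| \to R/4$ for a ball of radius $R$ and $r/3$ for a long
tube of radius $r$ (digital masks add ≈ 0.5 voxel). Under this embedding
the sphere rule $|\overline{\phi}| > 12$ only fires for balls of radius
≈ 48 voxels, far above the size gate — with these units the rule is
effectively dormant and small spherical confounders are instead removed
by the size gate and the layer-domain grid. The thresholds remain
configuration values with the published defaults. The classification
order (sphere test before tube test) is fixed so the rule set is
deterministic.

**Region growing.** The reference intensity is the seed's initial mean
and is never updated — an updating mean lets the region drift and need
not reach a fixpoint. Growth is additionally capped at 5 voxels
(Euclidean) from the seed: with a pure intensity tolerance, noisy
low-contrast boundaries eventually leak. Growing is monotone in the
tolerance and idempotent once the intensity boundary binds.

**Surface extraction.** The zero level is triangulated by marching
tetrahedra (each grid cube split into the six tetrahedra sharing its main
diagonal, linear interpolation along sign-crossing edges). This choice
produces the same class of isosurface as table-driven marching cubes
without a 256-case table, at the cost of a slightly denser triangulation;
areas agree with closed forms within a few percent at the grid
resolutions used. The extracted surface is a *closed offset surface* at
44 voxels on both sides of the cell sheet, so its area is about twice the
mid-layer area; the global surface density divides by `area/2`.

**Density sampling points.** A vertex of the offset surface is 44 voxels
(77 µm at 1.75 µm) away from the sheet, so counting within a 100 µm ball
*around the vertex* would intersect the sheet in a disc of only
$\sqrt{100^2-77^2} = 64$ µm radius and bias the density low by a factor
of ≈ 0.4. Each vertex therefore carries a sampling point: its projection
back onto the sheet along the gradient of the smoothed distance field;
the neighbourhood is counted there.

**Edge-corrected summary density.** At desk scale (a 256³ volume is only
0.45 mm across) most surface vertices are within 100 µm of the dataset
border, where the counting disc extends beyond the sampled population and
the raw local density is biased low. The summary's area-weighted mean is
therefore a minus-sampling estimate: vertices are included only if their
sampling point keeps one neighbourhood radius of clearance from the cell
population's bounding box, on every axis along which the population
extends farther than the neighbourhood diameter. The uncorrected mean is
reported alongside. On the 43 mm³ scale of a real acquisition the border
fraction is negligible and the two estimates coincide.

**Conventions.** Axis order is (z, y, x) with 1-based voxel indices and
voxel centres at integer coordinates; all physical quantities are voxels
× `voxel_len_um`. Objects use 26-connectivity. The layer-domain cube grid
also uses 26-connectivity (configurable to 6): on a sparsely populated
grid — tens of cells across a handful of 50-voxel cubes — the folded
sheet frequently steps diagonally from one filled cube to the next, and
face-only adjacency would split the layer into fragments and silently
drop detected cells from the population. Region-of-interest origins in
file metadata are 0-based. Gaussian kernels are truncated at 4σ with
reflected boundaries.

## The synthetic phantom

The generator (`phantom_generate`) emulates the study conditions at desk
scale, with exact ground truth:

* a folded layer $z = z_0 + A\sin(2\pi x/L_x)\sin(2\pi y/L_y)$ with
  A = 45 µm and 450 µm wavelengths — one fold across the default 256³
  volume at 1.75 µm voxels;
* granular stratum below the sheet (intensity 0.52), molecular above
  (0.40, 100 µm thick), paraffin on top (0.20); the phase-shift ordering
  granular > molecular > paraffin matches the tissue;
* somata of radius 10.5 µm (4,849 µm³ ≈ 905 voxels, inside the 300–3000
  gate) at 0.62, placed on the sheet by dart throwing at 165 cells/mm²
  with minimum spacing $0.7/\sqrt{\rho}$ — about 26 cells on the default
  volume — each with a centred 1.5 µm nucleolus at 0.85, the brightest
  feature in the scene;
* tubular vessels (radius 3.5–6 µm) as persistent random walks confined
  to the tissue and kept clear of somata, and sub-300-voxel Corpora
  amylacea (radius 2.5–4 µm, intensity 0.75) placed at least 60 voxels
  off the layer;
* smooth linear and radial background gradients (the local-tomography
  artefact) and Gaussian noise with
  $\sigma = (I_{mol}-I_{par})/\mathrm{SNR}_{target}$, so the measured SNR
  (molecular vs. paraffin patches) recovers the target (13 by default, 5
  for the second-beamline condition).

Somata keep 20 voxels of clearance from the volume faces so that the
10-voxel border-rejection rule cannot clip planted cells; the evaluation
therefore compares detections against the *complete* planted cell list.

What the phantom deliberately does **not** model: granule-cell texture in
the granular stratum, partial-volume anisotropy, reconstruction streaks
or ring artefacts, dendritic trees on the 1.75 µm cells (a separate
single-cell tube-tree fixture, `phantom_dendrite_cell`, exercises the
dendrite mode), and non-spherical somata. Passing the phantom pipeline
therefore demonstrates the correctness and calibration of the chain on
clean, geometrically ideal scenes — not performance on real tomograms,
where soma ellipticity and texture will move the error above the phantom
value.

## Problem sizes and determinism

The package's own validation runs the full pipeline on the default 256³
phantom (about 17M voxels, ≈ 26 cells), which completes in a few minutes
on one CPU core; unit tests use 14³–211³ fixtures. All stochastic steps
(phantom generation, test fixtures) are seeded; `run_pipeline` re-seeds
the generator from the configuration's `seed`, and repeated runs are
bit-identical.

## Known limitations

* Touching cells are not split (no watershed); on the phantom the
  dart-throwing spacing prevents contact, on real data merged pairs would
  count as one.
* The corpus rule is dormant under the voxel-unit distance embedding (see
  above); spherical confounders are controlled by the size gate instead.
* `detection_error` uses greedy nearest-first matching, which can differ
  from optimal assignment in adversarial configurations; for somata
  spaced ≥ 50 µm and a 10 µm radius the two coincide (property-tested).
* The NRRD reader supports raw little-endian encodings only.
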