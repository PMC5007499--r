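# purkinje3d

Label-free, fully automatic detection and quantification of cerebellar
Purkinje cells in 3D X-ray phase-contrast tomograms.

Hard X-ray phase tomography resolves individual neurons in
paraffin-embedded brain tissue without staining: Purkinje cells — the
large neurons forming a one-cell-thick folded sheet between the
cerebellar molecular and granular layers — appear as bright ellipsoids
with a distinct nucleolus. `purkinje3d` implements the complete
post-reconstruction analysis for such volumes, for imaging scientists and
neuropathology groups who need cell counts, per-cell morphology and layer
surface densities from label-free tomograms:

* **Multi-scale Hessian (Frangi) vesselness filtering.** Per voxel the
  eigenvalues |λ₁| ≤ |λ₂| ≤ |λ₃| of the scale-normalised Hessian form the
  ratios R_a = |λ₂|/|λ₃|, R_b = |λ₁|/√(|λ₂λ₃|) and S = ‖λ‖₂, combined as

  V = (1 − e^(−R_a²/2α²)) · e^(−R_b²/2β²) · (1 − e^(−S²/2γ²)),

  maximised over scales (cell mode: scales 3–6 voxels, α = 0.2, β = 0.5,
  γ = 40; dendrite mode: scales 1–3 voxels, α = 0.5, β = 0.1, γ = 10).
* **Object extraction and geometric sorting**: 26-connected components,
  a 300–3000 voxel size gate, a 10-voxel border margin, and level-set
  (signed-distance) shape descriptors that separate cell bodies from
  blood vessels (size/mean² ratio) and Corpora amylacea (mean magnitude).
* **Cell refinement**: region growing with a 0.0385 intensity tolerance
  and Otsu-based nucleolus segmentation at the intensity maximum.
* **Layer manifold**: grid-connectivity selection of the layer
  population, a marching-tetrahedra zero-level surface of the smoothed
  distance-to-cells field, and local surface density in a 100 µm
  neighbourhood (cells/mm²).
* **Evaluation**: detection error against ground truth,
  signal-to-noise ratio |x̄_mol − x̄_par|/σ_par, and a whole-cerebellum
  scan-budget calculator.
* **A synthetic phantom generator** producing cerebellum-like tomograms
  (folded cell layer, vessels, Corpora amylacea, background gradients,
  calibrated noise) with exact ground truth, so the whole pipeline is
  testable at desk scale.

Volumes are plain 3D arrays with an isotropic voxel length in µm, read
and written as multi-page TIFF, NRRD, or raw binary with a JSON sidecar.

## Worked example

```r
library(purkinje3d)

# a synthetic cerebellum tomogram (256^3 voxels at 1.75 um) + ground truth
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, stage = "all", out_dir = "run1")
```

This prints, stage by stage (values for seed 1):

```
[phantom] generating 256x256x256 phantom (seed 1)
[detect] normalising and filtering (scales 3,4,5,6)
[detect] 33 objects: cell_candidate=26, rejected_border=1, rejected_size=6
[refine] region growing + nucleolus segmentation
[layer] selecting layer population from 26 candidates
[layer] area 0.406 mm^2, mean local density 158.1 /mm^2
[evaluate] TP 26 FP 0 FN 0 -> error 0.00%
[snr] measured SNR 12.56 (target 13.00)
```

Reading the output: 26 of the 33 raw connected components survive the
size and border gates and the level-set shape rules as Purkinje-cell
candidates (the size-rejected components are the planted vessels, whose
tubes exceed 3000 voxels, and the sub-300-voxel Corpora amylacea). All
26 planted cells are matched within 10 µm with no false positives, a 0 %
detection error. The refined cell masks average ≈ 5,000 µm³ against
4,849 µm³ planted, and the area-weighted mean local density on the
extracted layer manifold is 158.1 cells/mm² against 165/mm² planted. The
measured SNR recovers the generator's target of 13.

Per-cell results are in `res$cells` (centroids, volumes in µm³,
nucleolus positions), the object table in `res$object_table`, the layer
mesh with per-vertex densities in `res$surface` (written as binary PLY),
and the scan budget in `res$plan`:

```r
res$plan
#> <scan_plan> 1.3e+06 mm^3 brain x 10% cerebellum / 20 mm^3 per scan
#>   -> 6500 scans x 5 min = 23 day(s) of beam time
```

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/purkinje3d all --seed 42 --out run1
Rscript inst/cli/purkinje3d plan
Rscript inst/cli/purkinje3d detect --input volume.nrrd --out run2 \
    segmentation.response_threshold=0.15
```

See `vignettes/methods.Rmd` for the model, the parameter calibration and
the phantom's scope.

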