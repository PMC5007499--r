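Package: purkinje3d
Title: Label-Free Detection and Quantification of Purkinje Cells in 3D
    Phase-Contrast Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic pipeline for counting and quantifying cerebellar
    Purkinje cells in 3D X-ray phase-contrast tomograms without staining or
    contrast agents. Provides multi-scale Hessian (Frangi) vesselness
    filtering, connected-component extraction with size and border gates,
    level-set (signed distance) shape descriptors separating cell bodies from
    blood vessels and Corpora amylacea, intensity-tolerance region growing with
    Otsu-based nucleolus segmentation, extraction of the Purkinje-cell layer
    manifold from detected cell positions with local surface-density mapping,
    detection-error and signal-to-noise evaluation, a whole-organ scan-budget
    calculator, and a synthetic cerebellum phantom generator with exact ground
    truth for desk-scale validation. Volumes are read and written as multi-page
    TIFF, NRRD, or raw binary with a JSON sidecar.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
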