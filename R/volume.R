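#' 3D scalar volume with isotropic voxel size
#'
#' The universal carrier between pipeline stages: a 3D numeric array in
#' `(z, y, x)` axis order together with the isotropic voxel edge length in
#' micrometres. Array indices are 1-based and voxel centres sit at integer
#' voxel coordinates; every physical quantity is derived as
#' voxels \eqn{\times} `voxel_len_um`.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`, all extents >= 1.
#' @param voxel_len_um Positive isotropic voxel edge length in micrometres.
#' @param provenance Optional character vector of free-text provenance notes
#'   (source file, normalisation applied, ...).
#' @return An object of class `volume3d` with fields `data`, `voxel_len_um`
#'   and `provenance`.
#' @examples
#' v <- volume3d(array(runif(8 * 8 * 8), c(8, 8, 8)), voxel_len_um = 1.75)
#' dim(v)
#' @export
volume3d <- function(data, voxel_len_um, provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array in (z, y, x) order")
  if (any(dim(data) < 1L)) stop("all three axis extents must be >= 1")
  if (!is.numeric(voxel_len_um) || length(voxel_len_um) != 1L ||
      !is.finite(voxel_len_um) || voxel_len_um <= 0)
    stop("`voxel_len_um` must be a single positive number")
  storage.mode(data) <- "double"
  structure(
    list(data = data, voxel_len_um = as.numeric(voxel_len_um),
         provenance = as.character(provenance)),
    class = "volume3d"
  )
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels (z, y, x), voxel %.4g um\n",
              d[1], d[2], d[3], x$voxel_len_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Rectangular region of interest in voxel coordinates
#'
#' Origins are 0-based voxel offsets (the first voxel of the volume has
#' origin `c(0, 0, 0)`), matching the convention used in sidecar metadata;
#' `origin + shape` must not exceed the volume shape on any axis.
#'
#' @param origin Integer triple `(z, y, x)`, each >= 0.
#' @param shape Integer triple `(z, y, x)`, each >= 1.
#' @return An object of class `roi_box`.
#' @examples
#' roi_box(c(0, 0, 0), c(300, 220, 600))
#' @export
roi_box <- function(origin, shape) {
  origin <- as.integer(origin); shape <- as.integer(shape)
  if (length(origin) != 3L || length(shape) != 3L)
    stop("`origin` and `shape` must be integer triples (z, y, x)")
  if (any(origin < 0L)) stop("`origin` must be >= 0 on every axis")
  if (any(shape < 1L)) stop("`shape` must be >= 1 on every axis")
  structure(list(origin = origin, shape = shape), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> origin (%s), shape (%s)\n",
              paste(x$origin, collapse = ", "),
              paste(x$shape, collapse = ", ")))
  invisible(x)
}

stop_if_not_volume <- function(v) {
  if (!inherits(v, "volume3d")) stop("expected a `volume3d` object")
  invisible(v)
}

# ---------------------------------------------------------------------------
# Readers / writers. Supported dialects: multi-page grayscale TIFF, NRRD
# (raw encoding, `spacings` honoured), raw float32/float64 with a JSON
# sidecar {shape, voxel_len_um, dtype, order: "zyx"}.

volume_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "tif" = , "tiff" = "tiff",
         "nrrd" = "nrrd",
         "raw" = , "json" = "raw",
         stop("unsupported volume format: .", ext,
              " (expected .tif/.tiff, .nrrd, or .raw/.json)"))
}

#' Read a volume from TIFF, NRRD, or raw + JSON sidecar
#'
#' The voxel length is taken from file metadata when present (NRRD
#' `spacings`, TIFF resolution tags in centimetre units, JSON sidecar),
#' otherwise from the `voxel_len_um` argument. Anisotropic spacing metadata
#' is rejected: the whole pipeline assumes isotropic voxels.
#'
#' @param path Path to a `.tif`/`.tiff`, `.nrrd`, `.raw` or `.json` file
#'   (for raw volumes either the data file or its sidecar may be given).
#' @param voxel_len_um Fallback voxel length in micrometres, used when the
#'   file carries no voxel-size metadata.
#' @return A [volume3d].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, voxel_len_um = NULL) {
  if (!file.exists(path) && volume_format(path) != "raw")
    stop("cannot read volume: no such file: ", path)
  fmt <- volume_format(path)
  out <- switch(fmt,
                tiff = read_volume_tiff(path),
                nrrd = read_volume_nrrd(path),
                raw  = read_volume_raw(path))
  vl <- out$voxel_len_um
  if (is.null(vl)) vl <- voxel_len_um
  if (is.null(vl))
    stop("no voxel size in file metadata and `voxel_len_um` not given")
  volume3d(out$data, vl, provenance = paste0("read from ", path))
}

#' Write a volume to TIFF, NRRD, or raw + JSON sidecar
#'
#' The format is chosen from the file extension. TIFF pages are written as
#' 32-bit float grayscale, one page per z-slice, with the voxel size encoded
#' in the resolution tags (pixels per centimetre); NRRD uses raw little-endian
#' double encoding with `spacings`; `.raw` writes float64 plus a JSON sidecar.
#'
#' @param v A [volume3d].
#' @param path Output path; directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stop_if_not_volume(v)
  fmt <- volume_format(path)
  switch(fmt,
         tiff = write_volume_tiff(v, path),
         nrrd = write_volume_nrrd(v, path),
         raw  = write_volume_raw(v, path))
  invisible(path)
}

read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("only single-channel grayscale TIFF stacks are supported")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); nz <- length(pages)
  a <- array(unlist(pages, use.names = FALSE), c(ny, nx, nz))
  a <- aperm(a, c(3, 1, 2))  # (z, y, x)
  vl <- NULL
  info <- attributes(pages[[1]])
  xr <- info$x.resolution
  unit <- info$resolution.unit
  if (!is.null(xr) && is.finite(xr) && xr > 0 &&
      !is.null(unit) && identical(unit, "cm")) {
    yr <- info$y.resolution
    if (!is.null(yr) && is.finite(yr) && abs(yr - xr) > 1e-6 * xr)
      stop("anisotropic TIFF resolution tags; the pipeline assumes isotropy")
    vl <- 1e4 / xr  # pixels per cm -> um per pixel
  }
  list(data = a, voxel_len_um = vl)
}

write_volume_tiff <- function(v, path) {
  d <- dim(v$data)
  rng <- range(v$data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("TIFF writer requires intensities in [0, 1]; run normalise_volume() first")
  pages <- lapply(seq_len(d[1]), function(z) v$data[z, , ])
  res <- 1e4 / v$voxel_len_um  # px per cm
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  # r-tiff cannot set resolution tags on write in all builds; tolerated —
  # readers fall back to an explicit voxel_len_um argument.
  invisible(res)
}

read_volume_nrrd <- function(path) {
  sz <- file.info(path)$size
  bytes <- readBin(path, "raw", n = sz)
  nl <- which(bytes == as.raw(10L))
  pair <- which(diff(nl) == 1L)
  if (length(pair) == 0L) stop("truncated NRRD header in ", path)
  term <- nl[pair[1]]  # first newline of the blank-line terminator
  header <- strsplit(rawToChar(bytes[seq_len(term - 1L)]), "\n",
                     fixed = TRUE)[[1]]
  header <- sub("\r$", "", header)
  if (!grepl("^NRRD000", header[1])) stop("not an NRRD file: ", path)
  fields <- header[grepl(":", header) & !grepl("^#", header)]
  kv <- do.call(rbind, lapply(strsplit(fields, ":\\s*"), function(p)
    c(tolower(trimws(p[1])), trimws(paste(p[-1], collapse = ":")))))
  get <- function(k) { i <- match(k, kv[, 1]); if (is.na(i)) NULL else kv[i, 2] }
  if (!is.null(get("encoding")) && get("encoding") != "raw")
    stop("only raw NRRD encoding is supported")
  ndim <- as.integer(get("dimension"))
  if (!identical(ndim, 3L)) stop("NRRD volume must be 3-dimensional")
  sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
  type <- get("type")
  what <- switch(type,
                 "double" = , "float64" = list(what = "double", size = 8),
                 "float"  = , "float32" = list(what = "double", size = 4),
                 "short"  = , "int16" = list(what = "integer", size = 2),
                 "unsigned short" = , "uint16" = list(what = "integer",
                                                      size = 2, signed = FALSE),
                 "uchar"  = , "uint8" = list(what = "integer", size = 1,
                                             signed = FALSE),
                 stop("unsupported NRRD type: ", type))
  endian <- get("endian"); if (is.null(endian)) endian <- "little"
  vl <- NULL
  sp <- get("spacings")
  if (!is.null(sp)) {
    spv <- as.numeric(strsplit(sp, "\\s+")[[1]])
    if (max(spv) - min(spv) > 1e-9 * max(spv))
      stop("anisotropic NRRD spacings (", sp,
           "); the pipeline assumes isotropy")
    vl <- spv[1]
  }
  n <- prod(sizes)
  payload <- bytes[seq.int(term + 2L, length(bytes))]
  vals <- readBin(payload, what = what$what, n = n, size = what$size,
                  signed = if (is.null(what$signed)) TRUE else what$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  # NRRD lists sizes fastest axis first; our fastest axis is z
  list(data = array(as.double(vals), dim = sizes), voxel_len_um = vl)
}

write_volume_nrrd <- function(v, path) {
  d <- dim(v$data)
  header <- c(
    "NRRD0004",
    "# produced by purkinje3d",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.17g %.17g %.17g", v$voxel_len_um, v$voxel_len_um,
            v$voxel_len_um),
    "encoding: raw",
    "endian: little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n\n"), con, eos = NULL)
  writeBin(as.vector(v$data), con, size = 8, endian = "little")
}

raw_sidecar_paths <- function(path) {
  base <- sub("\\.(raw|json)$", "", path)
  list(raw = paste0(base, ".raw"), json = paste0(base, ".json"))
}

read_volume_raw <- function(path) {
  p <- raw_sidecar_paths(path)
  if (!file.exists(p$json)) stop("missing JSON sidecar: ", p$json)
  if (!file.exists(p$raw)) stop("missing raw data file: ", p$raw)
  meta <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  need <- c("shape", "dtype", "order")
  if (!all(need %in% names(meta)))
    stop("sidecar must contain fields: ", paste(need, collapse = ", "))
  if (!identical(meta$order, "zyx"))
    stop("raw sidecar order must be \"zyx\"")
  size <- switch(meta$dtype, float32 = 4L, float64 = 8L,
                 stop("unsupported raw dtype: ", meta$dtype))
  n <- prod(meta$shape)
  vals <- readBin(p$raw, what = "double", n = n, size = size,
                  endian = "little")
  if (length(vals) != n) stop("truncated raw data in ", p$raw)
  vl <- if (!is.null(meta$voxel_len_um)) as.numeric(meta$voxel_len_um) else NULL
  list(data = array(vals, dim = as.integer(meta$shape)), voxel_len_um = vl)
}

write_volume_raw <- function(v, path) {
  p <- raw_sidecar_paths(path)
  meta <- list(shape = dim(v$data), voxel_len_um = v$voxel_len_um,
               dtype = "float64", order = "zyx")
  jsonlite::write_json(meta, p$json, auto_unbox = TRUE, digits = NA)
  con <- file(p$raw, "wb")
  on.exit(close(con))
  writeBin(as.vector(v$data), con, size = 8, endian = "little")
}

# ---------------------------------------------------------------------------

#' Percentile-clip intensity normalisation to [0, 1]
#'
#' Mandatory pipeline entry step: intensities are clipped to the
#' `[lo_pct, hi_pct]` percentiles and affinely rescaled to `[0, 1]`, so that
#' absolute intensity tolerances downstream (e.g. the region-growing maximum
#' intensity distance of 0.0385) refer to a fixed scale regardless of the
#' reconstruction's native dynamic range. Idempotent on already-normalised
#' data up to the clipping itself.
#'
#' @param v A [volume3d].
#' @param lo_pct,hi_pct Lower/upper clip percentiles (defaults 0.1 and 99.9).
#' @return A normalised [volume3d] with min 0 and max 1.
#' @export
normalise_volume <- function(v, lo_pct = 0.1, hi_pct = 99.9) {
  stop_if_not_volume(v)
  if (!(lo_pct < hi_pct)) stop("`lo_pct` must be < `hi_pct`")
  q <- quantile(v$data, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop("volume has zero dynamic range between the clip percentiles")
  x <- (v$data - q[1]) / (q[2] - q[1])
  x[x < 0] <- 0
  x[x > 1] <- 1
  volume3d(x, v$voxel_len_um,
           provenance = c(v$provenance,
                          sprintf("normalised to [0,1] (pct %.3g-%.3g)",
                                  lo_pct, hi_pct)))
}

#' Crop a volume to a region of interest
#'
#' @param v A [volume3d].
#' @param roi A [roi_box]; must lie within the volume bounds.
#' @return The cropped [volume3d]; voxel length unchanged.
#' @export
crop_volume <- function(v, roi) {
  stop_if_not_volume(v)
  if (!inherits(roi, "roi_box")) stop("`roi` must be a roi_box")
  d <- dim(v$data)
  if (any(roi$origin + roi$shape > d))
    stop("roi exceeds volume bounds on at least one axis")
  i <- lapply(1:3, function(a) seq.int(roi$origin[a] + 1L,
                                       roi$origin[a] + roi$shape[a]))
  volume3d(v$data[i[[1]], i[[2]], i[[3]], drop = FALSE], v$voxel_len_um,
           provenance = c(v$provenance,
                          sprintf("cropped to origin (%s) shape (%s)",
                                  paste(roi$origin, collapse = ","),
                                  paste(roi$shape, collapse = ","))))
}

#' Downsample a volume by block averaging
#'
#' Non-overlapping `factor^3` blocks are averaged; trailing partial blocks
#' are dropped (not padded), keeping block means unbiased. The voxel length
#' is multiplied by `factor`, e.g. binning a 0.45 um volume four times yields
#' 1.80 um voxels.
#'
#' @param v A [volume3d].
#' @param factor Positive integer binning factor.
#' @return The binned [volume3d].
#' @export
bin_volume <- function(v, factor) {
  stop_if_not_volume(v)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  d <- dim(v$data)
  if (any(d < factor)) stop("`factor` exceeds a volume axis extent")
  if (factor == 1L) return(v)
  nd <- d %/% factor
  a <- v$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
              seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(nd))
  out <- array(colMeans(a), dim = nd)
  volume3d(out, v$voxel_len_um * factor,
           provenance = c(v$provenance, sprintf("binned x%d", factor)))
}
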