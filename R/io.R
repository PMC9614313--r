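#' Read a 2-D image or label map from disk
#'
#' Two on-disk formats are supported:
#' * **NIfTI** (`.nii` / `.nii.gz`): single-slice images; pixel spacing is
#'   taken from `pixdim` and the origin from the qform offset.
#' * **PNG + JSON sidecar**: a 16-bit grayscale PNG (stored as two 8-bit
#'   channels) whose physical metadata lives in `<path>.json` with fields
#'   `spacing_mm`, `origin_mm` and `calibration` (`slope`, `intercept`)
#'   mapping stored integers back to calibrated densities.  A PNG without a
#'   sidecar is rejected because its spacing would be unknown.
#'
#' @param path file path.
#' @param format `"nifti"` or `"png"`; inferred from the extension when
#'   missing.
#' @param labels logical; read as a [labelmap2d()] instead of a [raster2d()].
#' @return a [raster2d()] or [labelmap2d()].
#' @export
read_image <- function(path, format = NULL, labels = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% .guess_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    sp <- RNifti::pixdim(img)[1]
    origin <- c(hdr$qoffset_x, hdr$qoffset_y)
    m <- as.array(img)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    vals <- t(structure(as.vector(m), dim = dim(m)))
    if (labels) labelmap2d(round(vals), spacing = sp, origin = origin)
    else raster2d(vals, spacing = sp, origin = origin)
  } else if (format == "png") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("spacing metadata required: PNG sidecar not found at ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    a <- png::readPNG(path)
    if (length(dim(a)) != 3L || dim(a)[3] != 2L)
      stop("expected a two-channel (16-bit split) grayscale PNG")
    ints <- round(a[, , 1] * 255) * 256 + round(a[, , 2] * 255)
    vals <- meta$calibration$intercept + meta$calibration$slope * ints
    if (labels)
      labelmap2d(round(vals), spacing = meta$spacing_mm,
                 origin = meta$origin_mm)
    else raster2d(vals, spacing = meta$spacing_mm, origin = meta$origin_mm)
  } else stop("unknown format: ", format)
}

#' Write a 2-D image or label map to disk
#'
#' Counterpart of [read_image()]; a write-then-read round trip reproduces
#' the value grid (exactly for NIfTI, within the 16-bit quantization step of
#' the calibration for PNG), the spacing and the origin.
#'
#' @param image a [raster2d()] or [labelmap2d()].
#' @param path output path (`.nii`/`.nii.gz`, or `.png`; the PNG sidecar is
#'   written next to it as `<path>.json`).
#' @param format `"nifti"` or `"png"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL) {
  format <- format %||% .guess_format(path)
  is_labels <- inherits(image, "labelmap2d")
  vals <- if (is_labels) image$labels else image$values
  if (format == "nifti") {
    nif <- RNifti::asNifti(t(vals))
    RNifti::pixdim(nif) <- c(image$spacing, image$spacing)
    m <- diag(c(image$spacing, image$spacing, 1, 1))
    m[1, 4] <- image$origin[1]
    m[2, 4] <- image$origin[2]
    nif <- RNifti::`qform<-`(nif, structure(m, code = 2L))
    RNifti::writeNifti(nif, path)
  } else if (format == "png") {
    lo <- min(vals); hi <- max(vals)
    slope <- if (hi > lo) (hi - lo) / 65535 else 1
    ints <- round((vals - lo) / slope)
    a <- array(0, c(nrow(vals), ncol(vals), 2))
    a[, , 1] <- (ints %/% 256) / 255
    a[, , 2] <- (ints %% 256) / 255
    png::writePNG(a, path)
    jsonlite::write_json(
      list(spacing_mm = image$spacing, origin_mm = image$origin,
           calibration = list(slope = slope, intercept = lo),
           labels = is_labels),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else stop("unknown format: ", format)
  invisible(path)
}

.guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.png$", path)) "png"
  else stop("cannot infer image format from extension of: ", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
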