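#' @useDynLib pqctseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom stats rnorm runif sd lm coef pnorm pt quantile
#' @importFrom utils modifyList
NULL

# Tissue label codes used throughout (fixed external contract).
#' Tissue label codes
#'
#' Named integer vector mapping tissue names to the label codes used in all
#' label maps: 0 air/background, 1 trabecular bone (TB), 2 cortical bone (CB),
#' 3 muscle, 4 subcutaneous adipose tissue (SAT).
#' @export
tissue_codes <- c(air = 0L, trabecular = 1L, cortical = 2L,
                  muscle = 3L, sat = 4L)

#' Create a 2-D density-calibrated raster image
#'
#' A `raster2d` stores a height x width grid of density-calibrated
#' intensities together with its isotropic pixel spacing (mm) and the physical
#' offset of the centre of pixel (0,0).  Row index corresponds to the y axis,
#' column index to the x axis; pixel centres sit at
#' `x = origin[1] + col * spacing` with 0-based columns.
#'
#' @param values numeric matrix (height x width) of intensities.
#' @param spacing pixel spacing in mm (isotropic, > 0). Default 0.5.
#' @param origin length-2 numeric, mm offset of the centre of pixel (0,0).
#' @return object of class `raster2d`.
#' @export
raster2d <- function(values, spacing = 0.5, origin = c(0, 0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (mm)")
  if (nrow(values) < 8L || ncol(values) < 8L)
    stop("raster2d requires width and height >= 8 pixels")
  if (!all(is.finite(values)))
    stop("raster2d values must all be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "raster2d")
}

#' Create a 2-D tissue label map
#'
#' Shares the grid conventions of [raster2d()].  Labels must be drawn from
#' the five-code set in [tissue_codes].
#'
#' @param labels integer matrix of tissue codes.
#' @inheritParams raster2d
#' @return object of class `labelmap2d`.
#' @export
labelmap2d <- function(labels, spacing = 0.5, origin = c(0, 0)) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:4))
    stop("labels must be drawn from codes 0 (air), 1 (TB), 2 (CB), 3 (muscle), 4 (SAT)")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (mm)")
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "labelmap2d")
}

#' @export
print.raster2d <- function(x, ...) {
  cat(sprintf("<raster2d> %d x %d px, spacing %.3g mm, origin (%g, %g) mm\n",
              ncol(x$values), nrow(x$values), x$spacing,
              x$origin[1], x$origin[2]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.labelmap2d <- function(x, ...) {
  cat(sprintf("<labelmap2d> %d x %d px, spacing %.3g mm, labels {%s}\n",
              ncol(x$labels), nrow(x$labels), x$spacing,
              paste(sort(unique(as.vector(x$labels))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.raster2d <- function(x) dim(x$values)
#' @export
dim.labelmap2d <- function(x) dim(x$labels)

# Physical coordinates (mm) of every pixel centre: matrices X, Y the shape
# of the grid.
.pixel_grid <- function(obj) {
  d <- if (inherits(obj, "labelmap2d")) dim(obj$labels)
       else if (inherits(obj, "dispfield2d")) dim(obj$dx)
       else dim(obj$values)
  x <- obj$origin[1] + (seq_len(d[2]) - 1) * obj$spacing
  y <- obj$origin[2] + (seq_len(d[1]) - 1) * obj$spacing
  list(X = matrix(x, d[1], d[2], byrow = TRUE),
       Y = matrix(y, d[1], d[2]))
}

# Convert physical mm coordinates to continuous 0-based pixel indices.
.phys_to_px <- function(obj, PX, PY) {
  list(sx = (PX - obj$origin[1]) / obj$spacing,
       sy = (PY - obj$origin[2]) / obj$spacing)
}

#' Affine transform (pull-back / resampling convention)
#'
#' Maps target (subject-grid) physical coordinates into source (atlas)
#' physical coordinates:
#' `source = matrix %*% (p - center) + center + translation`.
#' When used with [warp_image()], the output image at pixel `p` takes the
#' source image value at the mapped point, so a single resampling pass
#' suffices.
#'
#' @param matrix 2x2 real matrix, must be invertible.
#' @param translation length-2 translation in mm.
#' @param center length-2 rotation/scaling centre in mm (default the origin).
#' @return object of class `affine2d`.
#' @export
affine2d <- function(matrix = diag(2), translation = c(0, 0),
                     center = c(0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  if (abs(det(matrix)) < 1e-8) stop("affine matrix must be invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> matrix:\n")
  print(round(x$matrix, 5))
  cat(sprintf("  translation (%g, %g) mm, center (%g, %g) mm\n",
              x$translation[1], x$translation[2], x$center[1], x$center[2]))
  invisible(x)
}

#' Dense displacement field on a target grid
#'
#' Per-pixel 2-vector displacements in mm, defined on the fixed (target)
#' grid and mapping target points into source space (pull-back convention):
#' resampling reads the source image at `p + (dx(p), dy(p))`.
#'
#' @param dx,dy numeric matrices of x/y displacement components (mm).
#' @param spacing pixel spacing in mm.
#' @param origin grid origin in mm.
#' @param inverse optional list with `dx`,`dy` matrices of the inverse field.
#' @return object of class `dispfield2d`.
#' @export
dispfield2d <- function(dx, dy, spacing = 0.5, origin = c(0, 0),
                        inverse = NULL) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  if (!identical(dim(dx), dim(dy)))
    stop("dx and dy must have identical dimensions")
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    stop("displacement components must be finite")
  structure(list(dx = dx, dy = dy, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), inverse = inverse),
            class = "dispfield2d")
}

#' @export
print.dispfield2d <- function(x, ...) {
  m <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<dispfield2d> %d x %d px, spacing %.3g mm, max |d| %.3g mm%s\n",
              ncol(x$dx), nrow(x$dx), x$spacing, max(m),
              if (!is.null(x$inverse)) ", inverse stored" else ""))
  invisible(x)
}

# Identity field matching a raster's grid.
identity_field <- function(ref) {
  d <- dim(ref)
  dispfield2d(matrix(0, d[1], d[2]), matrix(0, d[1], d[2]),
              spacing = ref$spacing, origin = ref$origin)
}

# Sample a displacement field (bilinear) at physical coords; coordinates
# are clamped to the grid (replicate boundary) so compositions remain
# well-behaved at the image border.
.field_at <- function(field, PX, PY) {
  px <- .phys_to_px(field, PX, PY)
  sx <- pmin(pmax(as.vector(px$sx), 0), ncol(field$dx) - 1)
  sy <- pmin(pmax(as.vector(px$sy), 0), nrow(field$dx) - 1)
  list(dx = matrix(cpp_sample_bilinear(field$dx, sx, sy, 0),
                   nrow(PX), ncol(PX)),
       dy = matrix(cpp_sample_bilinear(field$dy, sx, sy, 0),
                   nrow(PX), ncol(PX)))
}

# Source physical coordinates for a transform applied on grid (X, Y).
.source_coords <- function(transform, X, Y) {
  if (inherits(transform, "affine2d")) {
    A <- transform$matrix; t <- transform$translation; ce <- transform$center
    Xc <- X - ce[1]; Yc <- Y - ce[2]
    list(PX = A[1, 1] * Xc + A[1, 2] * Yc + ce[1] + t[1],
         PY = A[2, 1] * Xc + A[2, 2] * Yc + ce[2] + t[2])
  } else if (inherits(transform, "dispfield2d")) {
    if (!identical(dim(transform$dx), dim(X)))
      stop("displacement field dimensions do not match the image grid")
    list(PX = X + transform$dx, PY = Y + transform$dy)
  } else {
    stop("transform must be an affine2d or dispfield2d")
  }
}

#' Warp an image by an affine transform or displacement field
#'
#' Resamples `image` onto its own grid through the transform (pull-back
#' convention, see [affine2d()] and [dispfield2d()]).  Intensities are
#' interpolated bilinearly (`interp = "linear"`) or by nearest neighbour;
#' points mapped outside the source field of view are filled with the
#' background value 0 (air).
#'
#' @param image a [raster2d()].
#' @param transform an [affine2d()] or [dispfield2d()].
#' @param interp `"linear"` (default) or `"nearest"`.
#' @return warped [raster2d()] on the same grid.
#' @export
warp_image <- function(image, transform, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  g <- .pixel_grid(image)
  sc <- .source_coords(transform, g$X, g$Y)
  px <- .phys_to_px(image, sc$PX, sc$PY)
  d <- dim(image)
  v <- if (interp == "linear") {
    cpp_sample_bilinear(image$values, as.vector(px$sx), as.vector(px$sy), 0)
  } else {
    ints <- image$values; storage.mode(ints) <- "integer"
    as.numeric(cpp_sample_nearest(ints, as.vector(px$sx), as.vector(px$sy), 0L))
  }
  raster2d(matrix(v, d[1], d[2]), spacing = image$spacing,
           origin = image$origin)
}

#' Warp a label map (nearest-neighbour only)
#'
#' Label propagation uses nearest-neighbour interpolation so no label code
#' can be invented; out-of-view pixels become 0 (air).
#'
#' @param labels a [labelmap2d()].
#' @inheritParams warp_image
#' @return warped [labelmap2d()].
#' @export
warp_labels <- function(labels, transform) {
  g <- .pixel_grid(labels)
  sc <- .source_coords(transform, g$X, g$Y)
  px <- .phys_to_px(labels, sc$PX, sc$PY)
  d <- dim(labels)
  v <- cpp_sample_nearest(labels$labels, as.vector(px$sx),
                          as.vector(px$sy), 0L)
  labelmap2d(matrix(v, d[1], d[2]), spacing = labels$spacing,
             origin = labels$origin)
}

# Gaussian-blur a raster (sigma in pixels).
blur_raster <- function(image, sigma_px) {
  raster2d(cpp_gauss_blur(image$values, sigma_px),
           spacing = image$spacing, origin = image$origin)
}

# Downsample by an integer factor (blur then decimate); spacing scales.
downsample_raster <- function(image, factor) {
  if (factor == 1L) return(image)
  v <- cpp_gauss_blur(image$values, factor / 2)
  rows <- seq(1L, nrow(v), by = factor)
  cols <- seq(1L, ncol(v), by = factor)
  raster2d(v[rows, cols, drop = FALSE], spacing = image$spacing * factor,
           origin = image$origin)
}
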