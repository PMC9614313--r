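# Displacement-field algebra: composition, scaling-and-squaring exponential,
# fixed-point inversion, Jacobian determinant.  All fields follow the
# pull-back convention of dispfield2d() with components in mm.

#' Compose two displacement fields
#'
#' Returns the field of the composite resampling map "apply `first`, then
#' `second`": `u(x) = second(x) + first(x + second(x))`, so that
#' `warp_image(warp_image(img, first), second)` equals
#' `warp_image(img, compose_fields(first, second))` up to interpolation.
#'
#' @param first,second [dispfield2d()] objects on the same grid.
#' @return composed [dispfield2d()].
#' @export
compose_fields <- function(first, second) {
  g <- .pixel_grid(second)
  s <- .field_at(first, g$X + second$dx, g$Y + second$dy)
  dispfield2d(second$dx + s$dx, second$dy + s$dy,
              spacing = second$spacing, origin = second$origin)
}

#' Exponential of a stationary velocity field
#'
#' Scaling-and-squaring: the velocity is divided by `2^k` (with `k` chosen so
#' the largest scaled displacement is below half a pixel) and the resulting
#' small field is squared `k` times by self-composition.  Used by the
#' log-domain demons, where the transform is `exp(v)` and its inverse is
#' obtained by backward computation `exp(-v)`.
#'
#' @param v a [dispfield2d()] interpreted as a velocity field (mm).
#' @param with_inverse also compute and store `exp(-v)` in the result's
#'   `inverse` slot.
#' @return a [dispfield2d()] containing the exponentiated field.
#' @export
exp_field <- function(v, with_inverse = FALSE) {
  ex <- .exp_one(v)
  if (with_inverse) {
    neg <- dispfield2d(-v$dx, -v$dy, spacing = v$spacing, origin = v$origin)
    exn <- .exp_one(neg)
    ex$inverse <- list(dx = exn$dx, dy = exn$dy)
  }
  ex
}

.exp_one <- function(v) {
  mx <- max(sqrt(v$dx^2 + v$dy^2)) / v$spacing  # max displacement in px
  k <- if (mx <= 0) 0L else max(0L, as.integer(ceiling(log2(mx / 0.5))))
  d <- dispfield2d(v$dx / 2^k, v$dy / 2^k,
                   spacing = v$spacing, origin = v$origin)
  if (k > 0) for (i in seq_len(k)) d <- compose_fields(d, d)
  d
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration `w <- -u(x + w(x))`; converges for fields whose
#' Jacobian determinant stays positive.
#'
#' @param u a [dispfield2d()].
#' @param iters maximum fixed-point iterations.
#' @param tol stop when the mean update falls below `tol` mm.
#' @return the inverse [dispfield2d()].
#' @export
invert_field <- function(u, iters = 30L, tol = 1e-4) {
  g <- .pixel_grid(u)
  wx <- -u$dx; wy <- -u$dy
  for (i in seq_len(iters)) {
    s <- .field_at(u, g$X + wx, g$Y + wy)
    nx <- -s$dx; ny <- -s$dy
    delta <- mean(sqrt((nx - wx)^2 + (ny - wy)^2))
    wx <- nx; wy <- ny
    if (delta < tol) break
  }
  dispfield2d(wx, wy, spacing = u$spacing, origin = u$origin)
}

#' Jacobian determinant of the mapping x + u(x)
#'
#' Central finite differences on the interior, one-sided at the borders.
#' Positive everywhere for an orientation-preserving (diffeomorphic) map.
#'
#' @param u a [dispfield2d()].
#' @return matrix of per-pixel Jacobian determinants.
#' @export
jacobian_det <- function(u) {
  h <- u$spacing
  dxx <- .ddx(u$dx, h); dxy <- .ddy(u$dx, h)
  dyx <- .ddx(u$dy, h); dyy <- .ddy(u$dy, h)
  (1 + dxx) * (1 + dyy) - dxy * dyx
}

# d/dx (along columns) and d/dy (along rows), central differences, mm units.
.ddx <- function(m, h) {
  n <- ncol(m)
  out <- (m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]) /
    (h * rep(c(1, rep(2, n - 2), 1), each = nrow(m)))
  out
}
.ddy <- function(m, h) {
  n <- nrow(m)
  (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) /
    (h * matrix(c(1, rep(2, n - 2), 1), n, ncol(m)))
}

# Resample a field defined on a coarse grid onto a finer reference grid
# (values stay in mm; only the sampling grid changes).
resample_field <- function(u, ref) {
  g <- .pixel_grid(ref)
  s <- .field_at(u, g$X, g$Y)
  dispfield2d(s$dx, s$dy, spacing = ref$spacing, origin = ref$origin)
}

#' Mean inverse-composition residual of a displacement field
#'
#' Mean magnitude (in pixels) of `u` composed with its stored (or supplied)
#' inverse; near zero for mutually inverse fields.
#'
#' @param u a [dispfield2d()] (with a stored inverse unless `inv` is given).
#' @param inv optional explicit inverse field.
#' @return mean residual in pixels.
#' @export
field_inverse_residual <- function(u, inv = NULL) {
  if (is.null(inv)) {
    if (is.null(u$inverse)) stop("no inverse field available")
    inv <- dispfield2d(u$inverse$dx, u$inverse$dy,
                       spacing = u$spacing, origin = u$origin)
  }
  comp <- compose_fields(u, inv)
  mean(sqrt(comp$dx^2 + comp$dy^2)) / u$spacing
}
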