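# Free-form deformation: dense warp parameterized by a uniform lattice of
# cubic B-spline control points, optimized against Mattes mutual
# information with a thin-plate (second-order) bending-energy regularizer,
# in a coarse-to-fine hierarchy.

#' Cubic B-spline basis functions
#'
#' The four uniform cubic B-spline basis values at parameter `u` in [0, 1):
#' `B0 = (1-u)^3/6`, `B1 = (3u^3-6u^2+4)/6`, `B2 = (-3u^3+3u^2+3u+1)/6`,
#' `B3 = u^3/6`.  They form a partition of unity.
#'
#' @param u numeric vector in [0, 1).
#' @param deriv derivative order 0, 1 or 2 (with respect to `u`).
#' @return length(u) x 4 matrix of basis values.
#' @export
cubic_bspline_basis <- function(u, deriv = 0L) {
  if (deriv == 0L) {
    cbind((1 - u)^3 / 6,
          (3 * u^3 - 6 * u^2 + 4) / 6,
          (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
          u^3 / 6)
  } else if (deriv == 1L) {
    cbind(-(1 - u)^2 / 2,
          (9 * u^2 - 12 * u) / 6,
          (-9 * u^2 + 6 * u + 3) / 6,
          u^2 / 2)
  } else if (deriv == 2L) {
    cbind(1 - u, 3 * u - 2, 1 - 3 * u, u)
  } else stop("deriv must be 0, 1 or 2")
}

#' Create a control-point grid for free-form deformation
#'
#' A uniform lattice with spacing `delta_px` pixels, padded one cell beyond
#' the image domain on every side (4x4 control points support each pixel).
#' Control displacements start at zero and are stored in mm.
#'
#' @param ref a [raster2d()] defining the image domain.
#' @param delta_px control-point spacing in pixels (> 0).
#' @return object of class `ffd_grid`.
#' @export
ffd_grid <- function(ref, delta_px = 16) {
  if (delta_px <= 0) stop("delta_px must be > 0")
  d <- dim(ref)
  ncx <- floor((d[2] - 1) / delta_px) + 4L
  ncy <- floor((d[1] - 1) / delta_px) + 4L
  structure(list(phi_x = matrix(0, ncy, ncx), phi_y = matrix(0, ncy, ncx),
                 delta_px = delta_px, spacing = ref$spacing,
                 origin = ref$origin, dim = d),
            class = "ffd_grid")
}

# Per-axis interpolation tables for 0-based pixel positions `pos_px`:
# base storage index (1-based, first of the 4 support points) and the 4
# basis weights.
.ffd_axis <- function(pos_px, delta_px, deriv = 0L) {
  cell <- floor(pos_px / delta_px)
  u <- pos_px / delta_px - cell
  list(base = as.integer(cell) + 1L,       # storage index of point (cell-1)
       w = cubic_bspline_basis(u, deriv))
}

#' Evaluate an FFD displacement at arbitrary points
#'
#' Tensor-product cubic B-spline interpolation of the control displacements;
#' each point is influenced by its 4x4 support cells only.
#'
#' @param grid an [ffd_grid()].
#' @param points n x 2 matrix of physical (x, y) coordinates in mm.
#' @return n x 2 matrix of displacements (mm).
#' @export
ffd_displacement <- function(grid, points) {
  points <- matrix(points, ncol = 2)
  px <- (points[, 1] - grid$origin[1]) / grid$spacing
  py <- (points[, 2] - grid$origin[2]) / grid$spacing
  if (any(px < -grid$delta_px | px > (ncol(grid$phi_x) - 3) * grid$delta_px |
          py < -grid$delta_px | py > (nrow(grid$phi_x) - 3) * grid$delta_px))
    stop("point outside the padded control lattice")
  ax <- .ffd_axis(px, grid$delta_px)
  ay <- .ffd_axis(py, grid$delta_px)
  out <- matrix(0, nrow(points), 2)
  for (l in 0:3) for (m in 0:3) {
    idx <- cbind(ay$base + m, ax$base + l)
    w <- ay$w[, m + 1] * ax$w[, l + 1]
    out[, 1] <- out[, 1] + w * grid$phi_x[idx]
    out[, 2] <- out[, 2] + w * grid$phi_y[idx]
  }
  out
}

# Dense field evaluation on the image grid via separable weights.
# deriv_x / deriv_y select derivative order of the x / y axis bases
# (0, 1 or 2); derivatives are returned per mm^order.
.ffd_dense <- function(grid, deriv_x = 0L, deriv_y = 0L) {
  d <- grid$dim
  ax <- .ffd_axis(seq_len(d[2]) - 1, grid$delta_px, deriv_x)
  ay <- .ffd_axis(seq_len(d[1]) - 1, grid$delta_px, deriv_y)
  sc <- (grid$delta_px * grid$spacing)^(-(deriv_x + deriv_y))
  fx <- matrix(0, d[1], d[2]); fy <- matrix(0, d[1], d[2])
  for (l in 0:3) for (m in 0:3) {
    w <- outer(ay$w[, m + 1], ax$w[, l + 1])
    px <- grid$phi_x[ay$base + m, ax$base + l]
    py <- grid$phi_y[ay$base + m, ax$base + l]
    fx <- fx + w * px
    fy <- fy + w * py
  }
  list(fx = fx * sc, fy = fy * sc)
}

#' Dense displacement field of an FFD lattice
#'
#' @param grid an [ffd_grid()].
#' @return a [dispfield2d()] sampled at every pixel of the lattice's domain.
#' @export
ffd_field <- function(grid) {
  f <- .ffd_dense(grid)
  dispfield2d(f$fx, f$fy, spacing = grid$spacing, origin = grid$origin)
}

#' Thin-plate bending energy of an FFD
#'
#' Domain-normalized integral (pixel average) of the squared second-order
#' spatial derivatives of the displacement field,
#' `mean(t_xx^2 + 2 t_xy^2 + t_yy^2)` summed over both components.  Zero
#' exactly when the lattice encodes a globally affine field.
#'
#' @param grid an [ffd_grid()].
#' @return non-negative scalar.
#' @export
bending_energy <- function(grid) {
  dxx <- .ffd_dense(grid, 2L, 0L)
  dxy <- .ffd_dense(grid, 1L, 1L)
  dyy <- .ffd_dense(grid, 0L, 2L)
  mean(dxx$fx^2 + 2 * dxy$fx^2 + dyy$fx^2 +
       dxx$fy^2 + 2 * dxy$fy^2 + dyy$fy^2)
}

# Scatter per-pixel quantities G (H x W) onto the control lattice with the
# separable weight tables ax, ay: returns dE/dphi for one component.
.ffd_scatter <- function(G, ax, ay, ncy, ncx) {
  out <- matrix(0, ncy, ncx)
  for (m in 0:3) {
    rs <- rowsum(G * ay$w[, m + 1], ay$base + m)  # collapse rows
    ridx <- as.integer(rownames(rs))
    for (l in 0:3) {
      cs <- t(rowsum(t(rs) * ax$w[, l + 1], ax$base + l))
      cidx <- as.integer(colnames(cs))
      out[ridx, cidx] <- out[ridx, cidx] + cs
    }
  }
  out
}

#' Hierarchical FFD registration
#'
#' Minimizes `lambda_sim * MI + lambda_reg * bending` over the control
#' displacements with L-BFGS-B (analytic gradient via the chain rule),
#' first on a coarse lattice, whose solution initializes the fine lattice.
#' The moving image is expected to be affinely pre-aligned.
#'
#' @param fixed subject image ([raster2d()]).
#' @param moving affinely pre-aligned atlas image ([raster2d()]).
#' @param config a [registration_config()].
#' @return a [dispfield2d()] (pull-back, mm) with attributes
#'   `energy_initial`, `energy_final`, `grid` (the final [ffd_grid()]) and
#'   `converged`.
#' @export
register_ffd <- function(fixed, moving, config = registration_config()) {
  deltas <- config$ffd$delta_px
  maxit <- rep_len(config$ffd$max_iter, length(deltas))
  grid <- NULL
  e0_first <- NULL
  converged <- TRUE
  for (li in seq_along(deltas)) {
    newg <- ffd_grid(fixed, deltas[li])
    if (!is.null(grid)) {
      # initialize fine control displacements from the coarse solution
      cpx <- (seq_len(ncol(newg$phi_x)) - 2) * newg$delta_px
      cpy <- (seq_len(nrow(newg$phi_x)) - 2) * newg$delta_px
      pts <- cbind(rep(cpx, each = length(cpy)), rep(cpy, length(cpx)))
      pts_mm <- cbind(newg$origin[1] + pts[, 1] * newg$spacing,
                      newg$origin[2] + pts[, 2] * newg$spacing)
      pts_mm[, 1] <- pmin(pmax(pts_mm[, 1], 0), (newg$dim[2] - 1) * newg$spacing)
      pts_mm[, 2] <- pmin(pmax(pts_mm[, 2], 0), (newg$dim[1] - 1) * newg$spacing)
      disp <- ffd_displacement(grid, pts_mm)
      newg$phi_x <- matrix(disp[, 1], nrow(newg$phi_x), ncol(newg$phi_x))
      newg$phi_y <- matrix(disp[, 2], nrow(newg$phi_x), ncol(newg$phi_x))
    }
    grid <- newg
    res <- .ffd_optimize(fixed, moving, grid, config, maxit[li])
    grid <- res$grid
    if (li == 1L) e0_first <- res$energy_initial
    if (!res$converged) converged <- FALSE
  }
  if (!converged)
    warning("FFD optimizer stopped at its iteration cap; returning best-so-far")
  out <- ffd_field(grid)
  attr(out, "energy_initial") <- e0_first
  attr(out, "energy_final") <- res$energy_final
  attr(out, "grid") <- grid
  attr(out, "converged") <- converged
  out
}

.ffd_optimize <- function(fixed, moving, grid, config, maxit) {
  d <- grid$dim
  ncy <- nrow(grid$phi_x); ncx <- ncol(grid$phi_x)
  npar <- ncy * ncx
  ax0 <- .ffd_axis(seq_len(d[2]) - 1, grid$delta_px, 0L)
  ay0 <- .ffd_axis(seq_len(d[1]) - 1, grid$delta_px, 0L)
  ax1 <- .ffd_axis(seq_len(d[2]) - 1, grid$delta_px, 1L)
  ay1 <- .ffd_axis(seq_len(d[1]) - 1, grid$delta_px, 1L)
  ax2 <- .ffd_axis(seq_len(d[2]) - 1, grid$delta_px, 2L)
  ay2 <- .ffd_axis(seq_len(d[1]) - 1, grid$delta_px, 2L)
  g <- .pixel_grid(fixed)
  ds <- grid$delta_px * grid$spacing
  npx <- prod(d)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL

  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    gr <- grid
    gr$phi_x <- matrix(par[1:npar], ncy, ncx)
    gr$phi_y <- matrix(par[npar + 1:npar], ncy, ncx)
    fld <- .ffd_dense(gr)
    px <- .phys_to_px(moving, g$X + fld$fx, g$Y + fld$fy)
    wv <- matrix(cpp_sample_bilinear(moving$values, as.vector(px$sx),
                                     as.vector(px$sy), 0), d[1], d[2])
    mi <- .mi_core(fixed$values, wv, config$bins, want_grad = TRUE)
    # spatial gradient of the warped moving image (per mm)
    gx <- .ddx(wv, fixed$spacing); gy <- .ddy(wv, fixed$spacing)
    # bending energy and its dense second-derivative fields
    dxx <- .ffd_dense_from(gr, ax2, ay0, 2L)
    dxy <- .ffd_dense_from(gr, ax1, ay1, 2L)
    dyy <- .ffd_dense_from(gr, ax0, ay2, 2L)
    be <- mean(dxx$fx^2 + 2 * dxy$fx^2 + dyy$fx^2 +
               dxx$fy^2 + 2 * dxy$fy^2 + dyy$fy^2)
    energy <- config$lambda_sim * (-mi$zeta) + config$lambda_reg * be
    # gradient: similarity part (chain rule through the warped intensities)
    dE_dm <- -config$lambda_sim * mi$dzeta_dm
    gpx <- .ffd_scatter(dE_dm * gx, ax0, ay0, ncy, ncx)
    gpy <- .ffd_scatter(dE_dm * gy, ax0, ay0, ncy, ncx)
    # gradient: bending part (analytic, same scatter machinery)
    bx <- (2 / npx) *
      (.ffd_scatter(dxx$fx, ax2, ay0, ncy, ncx) +
       2 * .ffd_scatter(dxy$fx, ax1, ay1, ncy, ncx) +
       .ffd_scatter(dyy$fx, ax0, ay2, ncy, ncx)) / ds^2
    by <- (2 / npx) *
      (.ffd_scatter(dxx$fy, ax2, ay0, ncy, ncx) +
       2 * .ffd_scatter(dxy$fy, ax1, ay1, ncy, ncx) +
       .ffd_scatter(dyy$fy, ax0, ay2, ncy, ncx)) / ds^2
    grad <- c(as.vector(gpx + config$lambda_reg * bx),
              as.vector(gpy + config$lambda_reg * by))
    cache$par <- par
    cache$val <- list(energy = energy, grad = grad, grid = gr)
    cache$val
  }

  par0 <- c(as.vector(grid$phi_x), as.vector(grid$phi_y))
  e0 <- evaluate(par0)$energy
  opt <- stats::optim(par0, fn = function(p) evaluate(p)$energy,
                      gr = function(p) evaluate(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit))
  best <- evaluate(opt$par)
  # 0 = converged; 52 = line search exhausted at a stationary point (treated
  # as converged); 1 = iteration cap reached
  list(grid = best$grid, energy_initial = e0,
       energy_final = min(opt$value, e0),
       converged = opt$convergence %in% c(0L, 52L))
}

# Dense evaluation from precomputed axis tables; order = total derivative
# order used for the physical scaling.
.ffd_dense_from <- function(grid, ax, ay, order) {
  d <- grid$dim
  sc <- (grid$delta_px * grid$spacing)^(-order)
  fx <- matrix(0, d[1], d[2]); fy <- matrix(0, d[1], d[2])
  for (l in 0:3) for (m in 0:3) {
    w <- outer(ay$w[, m + 1], ax$w[, l + 1])
    fx <- fx + w * grid$phi_x[ay$base + m, ax$base + l]
    fy <- fy + w * grid$phi_y[ay$base + m, ax$base + l]
  }
  list(fx = fx * sc, fy = fy * sc)
}
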