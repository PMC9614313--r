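# Log-domain symmetric diffeomorphic demons.  The transform is maintained
# as the exponential of a stationary velocity field, so the inverse is
# always available as exp(-v); forward and backward update forces are
# averaged antisymmetrically and composed into the velocity (first-order
# BCH), with fluid-like smoothing of the update and elastic-like smoothing
# of the velocity.

#' Demons update force
#'
#' Per-pixel update
#' `u(x) = -(S(x) - M(x)) * J(x) / (||J(x)||^2 + r(x)^2 / lambda_h^2)`
#' where `M` is the warped moving image, `J` its spatial intensity gradient
#' (per mm), `r(x) = S(x) - M(x)` the local residual (the per-pixel
#' correspondence error term), and `lambda_h` the spatial uncertainty on the
#' correspondences.  `u = 0` wherever both the gradient and the residual
#' vanish, and the magnitude obeys the step bound `|u| <= lambda_h / 2`
#' (arithmetic-geometric mean inequality on the denominator).  The update
#' is invariant under common rescaling of both images.
#'
#' @param fixed subject image `S` ([raster2d()]).
#' @param warped_moving the moving image already resampled onto the fixed
#'   grid ([raster2d()]).
#' @param lambda_h2 squared correspondence uncertainty `lambda_h^2` in
#'   mm^2; default the squared pixel spacing (maximum step of half a
#'   pixel).
#' @return a [dispfield2d()] holding the update force (mm).
#' @export
demons_update <- function(fixed, warped_moving, lambda_h2 = NULL) {
  if (!identical(dim(fixed), dim(warped_moving)))
    stop("images must share a grid")
  lambda_h2 <- lambda_h2 %||% fixed$spacing^2
  if (lambda_h2 <= 0) stop("lambda_h2 must be > 0")
  u <- .gn_step(fixed$values, warped_moving$values, fixed$spacing, lambda_h2)
  dispfield2d(-u$dx, -u$dy, spacing = fixed$spacing, origin = fixed$origin)
}

# Residual-reducing Gauss-Newton step under the pull-back convention
# (the negative of the demons_update force).  Pixels where gradient and
# residual both vanish get a zero step.
.gn_step <- function(fixed_vals, warped_vals, spacing, lambda_h2) {
  r <- fixed_vals - warped_vals
  gx <- .ddx(warped_vals, spacing)
  gy <- .ddy(warped_vals, spacing)
  den <- gx^2 + gy^2 + r^2 / lambda_h2
  den[den == 0] <- Inf
  list(dx = r * gx / den, dy = r * gy / den, mse = mean(r^2))
}

#' Symmetric diffeomorphic demons registration
#'
#' Multiresolution log-domain demons: at each iteration the forward force
#' (fixed vs moving warped by `exp(v)`) and backward force (moving vs fixed
#' warped by `exp(-v)`) are averaged antisymmetrically, smoothed with a
#' fluid-like Gaussian, composed into the velocity by first-order BCH
#' (`v <- v + eps * u`), and the velocity is smoothed with an elastic-like
#' Gaussian.  The symmetric mean-squared energy is tracked; if it fails to
#' improve for `n_div` consecutive iterations the best state is restored
#' and the level stops (with a warning only when the energy actually
#' diverged above its starting value).  Deterministic: no stochastic
#' sampling, fixed iteration order.
#'
#' @param fixed subject image ([raster2d()]).
#' @param moving affinely pre-aligned atlas image ([raster2d()]).
#' @param config a [registration_config()].
#' @return list with `forward` and `inverse` [dispfield2d()] (mutually
#'   inverse pull-back fields; `forward` also stores its inverse), `energy`
#'   (per-iteration symmetric MSE trace across levels) and `converged`.
#' @export
register_sdd <- function(fixed, moving, config = registration_config()) {
  dcfg <- config$demons
  lh2 <- dcfg$lambda_h2 %||% fixed$spacing^2

  factors <- rev(2^(seq_len(dcfg$levels) - 1))   # e.g. 4, 2, 1
  factors <- factors[factors < min(dim(fixed)) / 8]
  if (!length(factors)) factors <- 1L
  v <- NULL
  trace <- numeric(0)
  converged <- TRUE

  for (f in factors) {
    fx <- downsample_raster(fixed, f)
    mv <- downsample_raster(moving, f)
    v <- if (is.null(v)) identity_field(fx) else resample_field(v, fx)
    best <- v; best_e <- Inf; first_e <- NA_real_; bad <- 0L
    for (it in seq_len(dcfg$iters)) {
      tau <- .exp_one(v)
      taui <- .exp_one(dispfield2d(-v$dx, -v$dy, v$spacing, v$origin))
      wm <- warp_image(mv, tau)
      ws <- warp_image(fx, taui)
      fwd <- .gn_step(fx$values, wm$values, fx$spacing, lh2)
      bwd <- .gn_step(mv$values, ws$values, fx$spacing, lh2)
      e <- (fwd$mse + bwd$mse) / 2
      if (it == 1L) first_e <- e
      trace <- c(trace, e)
      if (e < best_e) { best_e <- e; best <- v; bad <- 0L }
      else {
        bad <- bad + 1L
        if (bad >= dcfg$n_div) {
          if (best_e > first_e) converged <- FALSE
          break
        }
      }
      ux <- cpp_gauss_blur((fwd$dx - bwd$dx) / 2, dcfg$sigma_fluid)
      uy <- cpp_gauss_blur((fwd$dy - bwd$dy) / 2, dcfg$sigma_fluid)
      vx <- cpp_gauss_blur(v$dx + dcfg$eps * ux, dcfg$sigma_elastic)
      vy <- cpp_gauss_blur(v$dy + dcfg$eps * uy, dcfg$sigma_elastic)
      v <- dispfield2d(vx, vy, v$spacing, v$origin)
    }
    v <- best
  }
  if (!converged)
    warning("demons energy diverged; reverted to the best state")

  fwd <- exp_field(v, with_inverse = TRUE)
  inv <- dispfield2d(fwd$inverse$dx, fwd$inverse$dy, v$spacing, v$origin,
                     inverse = list(dx = fwd$dx, dy = fwd$dy))
  list(forward = fwd, inverse = inv, energy = trace, converged = converged)
}
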