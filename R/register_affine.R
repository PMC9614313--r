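# Linear (affine) registration by Mattes mutual information and a
# regular-step gradient descent optimizer, in a 2-level multiresolution
# pyramid.  All registrars in the package estimate pull-back transforms:
# the result maps subject (fixed) coordinates into atlas (moving)
# coordinates so the moving image can be resampled in one pass.

#' Registration configuration
#'
#' Constants for the three registration engines.  Every value can be
#' overridden; see the methods vignette for the reasoning behind the
#' defaults.
#'
#' @param bins MI histogram bins per axis (>= 8).
#' @param lambda_sim similarity weight multiplying mutual information in the
#'   deformable energy (negative: MI is maximized).
#' @param lambda_reg bending-energy weight for the FFD.
#' @param affine list: `levels`, `max_iter` (per level), `init_step` /
#'   `min_step` (mm), `fd_step` (finite-difference step, mm).
#' @param ffd list: `delta_px` (control spacings, coarse to fine),
#'   `max_iter` per level.
#' @param demons list: `levels`, `iters` per level, `sigma_fluid` /
#'   `sigma_elastic` (px), `eps` step weight in (0,1], `lambda_h2` squared
#'   correspondence uncertainty in mm^2 (NULL: squared pixel spacing),
#'   `n_div` consecutive non-improving iterations tolerated before a level
#'   stops.
#' @return nested list of class `registration_config`.
#' @export
registration_config <- function(bins = 32L, lambda_sim = -1, lambda_reg = 0.01,
                                affine = list(), ffd = list(),
                                demons = list()) {
  if (bins < 8L) stop("bins must be >= 8")
  cfg <- list(
    bins = as.integer(bins), lambda_sim = lambda_sim,
    lambda_reg = lambda_reg,
    affine = modifyList(list(levels = 2L, max_iter = 120L, init_step = 2,
                             min_step = 0.01, fd_step = 0.3), affine),
    ffd = modifyList(list(delta_px = c(16L, 8L), max_iter = c(60L, 40L)),
                     ffd),
    demons = modifyList(list(levels = 3L, iters = 50L, sigma_fluid = 2,
                             sigma_elastic = 1, eps = 1, lambda_h2 = NULL,
                             n_div = 5L), demons))
  if (cfg$affine$max_iter < 1L || any(cfg$ffd$max_iter < 1L) ||
      cfg$demons$iters < 1L)
    stop("iteration caps must be >= 1")
  if (cfg$demons$eps <= 0 || cfg$demons$eps > 1)
    stop("demons eps must lie in (0, 1]")
  structure(cfg, class = "registration_config")
}

# Intensity-weighted centroid in physical coordinates.
.centroid <- function(image) {
  v <- image$values - min(image$values)
  s <- sum(v)
  if (s <= 0) return(c(mean(.pixel_grid(image)$X), mean(.pixel_grid(image)$Y)))
  g <- .pixel_grid(image)
  c(sum(g$X * v), sum(g$Y * v)) / s
}

# Map 6 working parameters to an affine2d.  The linear part is expressed as
# a deviation from the identity scaled by the half field extent, so all six
# parameters live on a comparable mm-like scale for the optimizer.
.par_to_affine <- function(q, center, r_scale) {
  affine2d(matrix = diag(2) + matrix(q[1:4] / r_scale, 2, 2),
           translation = q[5:6], center = center)
}

#' Affine registration by Mattes mutual information
#'
#' Estimates the pull-back affine transform `mu` minimizing the negative
#' mutual information between `fixed` and `warp_image(moving, mu)`, using a
#' regular step gradient descent optimizer (step halved whenever a trial
#' step fails to decrease the energy) inside a 2-level multiresolution
#' pyramid.  Initialization aligns the intensity centroids.  Deterministic
#' given the configuration.
#'
#' @param fixed subject image ([raster2d()]).
#' @param moving atlas image ([raster2d()]).
#' @param config a [registration_config()].
#' @return an [affine2d()] with attributes `energy` (final negative MI) and
#'   `converged` (FALSE if an iteration cap was hit, with a warning).
#' @export
register_affine <- function(fixed, moving, config = registration_config()) {
  acfg <- config$affine
  center <- .centroid(fixed)
  r_scale <- max(dim(fixed)) * fixed$spacing / 2
  q <- c(0, 0, 0, 0, .centroid(moving) - center)

  factors <- rev(2^(seq_len(acfg$levels) - 1))   # e.g. 2, 1
  converged <- TRUE
  for (f in factors) {
    fx <- downsample_raster(fixed, f)
    mv <- downsample_raster(moving, f)
    en <- function(qq) {
      tr <- .par_to_affine(qq, center, r_scale)
      as.numeric(mattes_mi(fx, warp_image(mv, tr), config$bins))
    }
    st <- acfg$init_step * f
    e <- en(q)
    h <- acfg$fd_step
    iter <- 0L
    while (st >= acfg$min_step && iter < acfg$max_iter) {
      iter <- iter + 1L
      g <- vapply(seq_along(q), function(k) {
        qp <- q; qm <- q
        qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
        (en(qp) - en(qm)) / (2 * h)
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (!is.finite(gn) || gn < 1e-12) break
      cand <- q - st * g / gn
      ec <- en(cand)
      if (is.finite(ec) && ec < e) { q <- cand; e <- ec } else st <- st / 2
    }
    if (iter >= acfg$max_iter) converged <- FALSE
  }
  if (!converged)
    warning("affine registration hit the iteration cap; returning best-so-far")
  out <- .par_to_affine(q, center, r_scale)
  attr(out, "energy") <- e
  attr(out, "converged") <- converged
  out
}
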