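# Shared fixtures: small phantoms and a reduced-effort registration
# configuration for unit tests (the acceptance tests use the defaults).

tiny_phantom <- function(seed = 3, site = 66, size = 64, ...) {
  generate_phantom(phantom_spec(site = site, seed = seed,
                                image_size = size, ...))
}

# a smooth, noise-free test image (Gaussian blobs) for interpolation checks
smooth_test_image <- function(size = 64, spacing = 0.5) {
  x <- seq(-1, 1, length.out = size)
  X <- matrix(x, size, size, byrow = TRUE)
  Y <- matrix(x, size, size)
  v <- 400 * exp(-((X - 0.2)^2 + (Y + 0.1)^2) / 0.18) +
       250 * exp(-((X + 0.4)^2 + (Y - 0.3)^2) / 0.08)
  raster2d(v, spacing = spacing)
}

quick_config <- function() {
  registration_config(
    affine = list(max_iter = 60L),
    ffd = list(max_iter = c(40L, 25L)),
    demons = list(iters = 30L))
}
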