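# Registration engines: mutual information, affine, B-spline FFD,
# log-domain symmetric diffeomorphic demons.

test_that("mutual information behaves as a similarity measure", {
  S <- tiny_phantom()$image
  con <- raster2d(matrix(7, 64, 64), spacing = 0.5)
  z <- mattes_mi(S, con)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_lte(as.numeric(mattes_mi(S, S)), 0)
  sh <- warp_image(S, affine2d(translation = c(2.5, 0)))
  expect_lt(as.numeric(mattes_mi(S, S)), as.numeric(mattes_mi(S, sh)))
  expect_lt(abs(as.numeric(mattes_mi(S, sh)) - as.numeric(mattes_mi(sh, S))),
            1e-9)
  expect_error(mattes_mi(S, S, bins = 4), "bins")
})

test_that("affine registration recovers identity, translation, rotation", {
  S <- tiny_phantom()$image
  mu0 <- register_affine(S, S)
  expect_lt(sqrt(sum(mu0$translation^2)), 0.1)          # < 0.2 px
  expect_lt(abs(atan2(mu0$matrix[2, 1], mu0$matrix[1, 1])) * 180 / pi, 0.5)

  known_t <- c(3.5, -2)
  mv <- warp_image(S, affine2d(translation = known_t))
  mu <- register_affine(S, mv)
  # pull-back: recovered translation is the negative of the applied one
  expect_lt(max(abs(mu$translation + known_t)), 0.25)   # within 0.5 px

  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(15.75, 15.75)
  mvr <- warp_image(S, affine2d(matrix = R, center = ctr))
  mur <- register_affine(S, mvr)
  ang <- atan2(mur$matrix[2, 1], mur$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang + 10), 1)                           # within 1 degree
})

test_that("cubic B-spline basis partitions unity and FFD has local support", {
  u <- seq(0, 1 - 1e-9, length.out = 101)
  expect_equal(rowSums(cubic_bspline_basis(u)), rep(1, 101), tolerance = 1e-12)
  S <- tiny_phantom()$image
  g <- ffd_grid(S, 8)
  pts <- cbind(runif(30, 0, 31.5), runif(30, 0, 31.5))
  expect_equal(max(abs(ffd_displacement(g, pts))), 0)
  # one displaced control point influences only its 4-cell neighbourhood
  g$phi_x[5, 6] <- 2
  f <- ffd_field(g)
  nz <- which(abs(f$dx) > 1e-12, arr.ind = TRUE)
  cp_px <- c((6 - 2) * 8, (5 - 2) * 8)   # (x, y) pixel position, 0-based
  expect_gte(min(nz[, 2]) - 1, cp_px[1] - 16)
  expect_lte(max(nz[, 2]) - 1, cp_px[1] + 16)
  expect_gte(min(nz[, 1]) - 1, cp_px[2] - 16)
  expect_lte(max(nz[, 1]) - 1, cp_px[2] + 16)
  expect_error(ffd_displacement(g, cbind(1e4, 0)), "outside")
})

test_that("bending energy vanishes on affine lattices and matches quadrature", {
  S <- tiny_phantom()$image
  g <- ffd_grid(S, 16)
  expect_equal(bending_energy(g), 0)
  # globally affine control displacements -> zero bending
  cpx <- (seq_len(ncol(g$phi_x)) - 2) * g$delta_px * g$spacing
  cpy <- (seq_len(nrow(g$phi_x)) - 2) * g$delta_px * g$spacing
  g$phi_x <- outer(rep(1, nrow(g$phi_x)), 0.3 * cpx) +
    matrix(0.1 * cpy, nrow(g$phi_x), ncol(g$phi_x)) + 2
  g$phi_y <- outer(0.2 * cpy, rep(1, ncol(g$phi_x))) - 1
  expect_lt(bending_energy(g), 1e-20)
  # single displaced control point: finite-difference quadrature oracle
  g2 <- ffd_grid(S, 8)
  g2$phi_x[5, 6] <- 2
  fld <- ffd_field(g2)
  h <- g2$spacing
  dxx <- function(m) (m[, c(2:ncol(m), ncol(m))] - 2 * m +
                        m[, c(1, 1:(ncol(m) - 1))]) / h^2
  dyy <- function(m) (m[c(2:nrow(m), nrow(m)), ] - 2 * m +
                        m[c(1, 1:(nrow(m) - 1)), ]) / h^2
  dxy <- function(m) pqctseg:::.ddx(pqctseg:::.ddy(m, h), h)
  fd <- mean(dxx(fld$dx)^2 + 2 * dxy(fld$dx)^2 + dyy(fld$dx)^2 +
             dxx(fld$dy)^2 + 2 * dxy(fld$dy)^2 + dyy(fld$dy)^2)
  expect_equal(bending_energy(g2), fd, tolerance = 0.1)
})

test_that("FFD registration is near-identity for identical images and
           recovers a known smooth warp", {
  ph <- tiny_phantom()
  S <- ph$image; L <- ph$labels
  f0 <- suppressWarnings(register_ffd(S, S, quick_config()))
  expect_lt(mean(sqrt(f0$dx^2 + f0$dy^2)) / S$spacing, 0.2)
  expect_lte(attr(f0, "energy_final"), attr(f0, "energy_initial"))

  w <- random_smooth_deformation(S, amplitude = 3, scale = 20, seed = 11)
  Sw <- warp_image(S, w); Lw <- warp_labels(L, w)
  f <- suppressWarnings(register_ffd(Sw, S))
  pred <- warp_labels(L, f)
  sc <- score_segmentation(pred, Lw)
  expect_true(all(sc$dsc >= 0.95))
  expect_lte(attr(f, "energy_final"), attr(f, "energy_initial"))
})

test_that("demons update follows the normalized-force formula", {
  # single-pixel evaluation: r = 2, J = (1, 0) per mm, r^2/lambda_h^2 = 1
  mv <- outer(rep(1, 8), 0:7) + 4.5       # gradient 1 per mm along x
  fx <- mv + 2                            # residual r = 2 everywhere
  u <- demons_update(raster2d(fx, spacing = 1), raster2d(mv, spacing = 1),
                     lambda_h2 = 4)
  expect_equal(u$dx[4, 4], -1)
  expect_equal(u$dy[4, 4], 0)
  # zero residual -> zero update
  z <- demons_update(raster2d(mv, spacing = 1), raster2d(mv, spacing = 1))
  expect_equal(max(abs(z$dx)), 0)
  # step bound |u| <= lambda_h / 2 everywhere
  S <- tiny_phantom()$image
  M <- tiny_phantom(seed = 8)$image
  for (lh2 in c(0.25, 1)) {
    u <- demons_update(S, M, lambda_h2 = lh2)
    expect_lte(max(sqrt(u$dx^2 + u$dy^2)), sqrt(lh2) / 2 + 1e-12)
  }
})

test_that("field exponential is exact for constants and invertible", {
  z <- dispfield2d(matrix(0, 16, 16), matrix(0, 16, 16), spacing = 0.5)
  e0 <- exp_field(z)
  expect_equal(max(abs(e0$dx)), 0)
  v <- dispfield2d(matrix(0.7, 64, 64), matrix(-0.4, 64, 64), spacing = 0.5)
  e <- exp_field(v, with_inverse = TRUE)
  expect_equal(max(abs(e$dx - 0.7)), 0)
  expect_equal(max(abs(e$dy + 0.4)), 0)
  img <- smooth_test_image()
  vr <- random_smooth_deformation(img, amplitude = 1, scale = 12, seed = 3,
                                  compute_inverse = FALSE)
  er <- exp_field(vr, with_inverse = TRUE)
  expect_lt(field_inverse_residual(er), 0.05)
})

test_that("symmetric demons recovers known warps with consistent inverses", {
  ph <- tiny_phantom()
  S <- ph$image; L <- ph$labels
  r0 <- register_sdd(S, S, quick_config())
  expect_lt(mean(sqrt(r0$forward$dx^2 + r0$forward$dy^2)) / S$spacing, 0.2)

  w <- random_smooth_deformation(S, amplitude = 3, scale = 20, seed = 11)
  Sw <- warp_image(S, w); Lw <- warp_labels(L, w)
  r <- register_sdd(Sw, S)
  pred <- warp_labels(L, r$forward)
  sc <- score_segmentation(pred, Lw)
  expect_true(all(sc$dsc >= 0.95))
  expect_lt(field_inverse_residual(r$forward), 0.1)
  expect_gt(min(jacobian_det(r$forward)), 0)
  # determinism
  r2 <- register_sdd(Sw, S)
  expect_identical(r$forward$dx, r2$forward$dx)
})
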