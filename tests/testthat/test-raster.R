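# Image/label data model, file round trips, warping and transforms.

test_that("constructors enforce the grid invariants", {
  expect_error(raster2d(matrix(1, 4, 4)), "width and height")
  expect_error(raster2d(matrix(c(1, NA, rep(1, 62)), 8, 8)), "finite")
  expect_error(raster2d(matrix(1, 8, 8), spacing = 0), "positive")
  expect_error(labelmap2d(matrix(5L, 8, 8)), "codes")
  expect_error(affine2d(matrix = matrix(0, 2, 2)), "invertible")
  expect_error(dispfield2d(matrix(0, 8, 8), matrix(0, 9, 8)), "identical")
})

test_that("NIfTI write-read round trip preserves values, spacing, origin", {
  ph <- tiny_phantom()
  img <- raster2d(ph$image$values, spacing = 0.5, origin = c(1.5, -2))
  f <- tempfile(fileext = ".nii.gz")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$spacing, 0.5)
  expect_equal(back$origin, c(1.5, -2))
  # label maps round trip with exact codes
  fl <- tempfile(fileext = ".nii.gz")
  write_image(ph$labels, fl)
  backl <- read_image(fl, labels = TRUE)
  expect_identical(backl$labels, ph$labels$labels)
})

test_that("PNG+sidecar round trip works and bare PNG is rejected", {
  img <- tiny_phantom()$image
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_image(f)
  rng <- diff(range(img$values))
  expect_lt(max(abs(back$values - img$values)), rng / 65535 + 1e-9)
  expect_equal(back$spacing, img$spacing)
  # remove the sidecar -> spacing unknown -> rejected
  file.remove(paste0(f, ".json"))
  expect_error(read_image(f), "spacing metadata required")
  expect_error(read_image(tempfile(fileext = ".png")), "not found")
  expect_error(read_image(f, format = "tiff"), "unknown format")
})

test_that("warp_image with the identity transform is exact", {
  img <- tiny_phantom()$image
  expect_identical(warp_image(img, affine2d())$values, img$values)
  zero <- dispfield2d(matrix(0, nrow(img$values), ncol(img$values)),
                      matrix(0, nrow(img$values), ncol(img$values)),
                      spacing = img$spacing)
  expect_identical(warp_image(img, zero)$values, img$values)
})

test_that("integer-pixel translation shifts columns and backfills with 0", {
  img <- tiny_phantom()$image
  w <- warp_image(img, affine2d(translation = c(2 * img$spacing, 0)))
  n <- ncol(img$values)
  expect_equal(w$values[, 1:(n - 2)], img$values[, 3:n])
  expect_true(all(w$values[, (n - 1):n] == 0))
})

test_that("warp then inverse-warp of a smooth image is near-identity inside", {
  img <- smooth_test_image()
  f <- random_smooth_deformation(img, amplitude = 2.5, scale = 15, seed = 4)
  inv <- dispfield2d(f$inverse$dx, f$inverse$dy, f$spacing, f$origin)
  back <- warp_image(warp_image(img, f), inv)
  interior <- 12:52
  err <- abs(back$values[interior, interior] - img$values[interior, interior])
  expect_lt(mean(err), 0.01 * diff(range(img$values)))
})

test_that("label warping is nearest-neighbour and cannot invent codes", {
  lab <- tiny_phantom()$labels
  expect_identical(warp_labels(lab, affine2d())$labels, lab$labels)
  f <- random_smooth_deformation(lab, amplitude = 3, scale = 12, seed = 9,
                                 compute_inverse = FALSE)
  w <- warp_labels(lab, f)
  expect_true(all(w$labels %in% unique(as.vector(lab$labels))))
  # integer-pixel translation moves labels exactly
  tr <- warp_labels(lab, affine2d(translation = c(lab$spacing * 3, 0)))
  n <- ncol(lab$labels)
  expect_identical(tr$labels[, 1:(n - 3)], lab$labels[, 4:n])
})

test_that("field composition matches sequential warping", {
  img <- smooth_test_image()
  f1 <- random_smooth_deformation(img, amplitude = 1.5, scale = 14, seed = 1,
                                  compute_inverse = FALSE)
  f2 <- random_smooth_deformation(img, amplitude = 1.5, scale = 14, seed = 2,
                                  compute_inverse = FALSE)
  seq2 <- warp_image(warp_image(img, f1), f2)
  once <- warp_image(img, compose_fields(f1, f2))
  interior <- 10:54
  expect_lt(mean(abs(seq2$values[interior, interior] -
                     once$values[interior, interior])), 2)
})
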