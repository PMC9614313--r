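# Single-atlas segmentation, STAPLE EM fusion, multi-atlas pipeline.

simulate_raters <- function(truth, sens, codes = 0:4, seed = 42) {
  withr::with_seed(seed, {
    sapply(sens, function(p) {
      e <- truth
      flip <- runif(length(truth)) > p
      e[flip] <- vapply(truth[flip],
                        function(tl) sample(setdiff(codes, tl), 1L),
                        numeric(1))
      as.integer(e)
    })
  })
}

test_that("segmenting the atlas itself returns its own labels", {
  ph <- tiny_phantom()
  for (eng in c("sdd", "ffd")) {
    pred <- suppressWarnings(
      segment_single_atlas(ph$image, ph$image, ph$labels, engine = eng,
                           config = quick_config()))
    expect_identical(dim(pred$labels), dim(ph$labels$labels))
    sc <- score_segmentation(pred, ph$labels)
    expect_true(all(sc$dsc >= 0.99))
  }
})

test_that("STAPLE recovers simulated rater sensitivities", {
  withr::with_seed(42, {
    truth <- sample(0:4, 10000, replace = TRUE,
                    prob = c(0.4, 0.15, 0.1, 0.25, 0.1))
  })
  sens <- c(0.95, 0.85, 0.75)
  dec <- simulate_raters(truth, sens)
  fit <- staple_fuse(dec)
  # class-frequency-weighted sensitivity per rater
  freq <- as.numeric(table(factor(truth, levels = 0:4))) / length(truth)
  p_hat <- as.numeric(fit$p %*% freq)
  expect_true(all(abs(p_hat - sens) <= 0.02))
  expect_true(all(diff(fit$log_likelihood) >= -1e-8))
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-9)
  # fused map beats every noisy rater
  expect_lt(mean(fit$labels != truth), min(colMeans(dec != truth)))
})

test_that("a perfect rater plus independent noisy raters fuse below the
           noisy error rates", {
  withr::with_seed(7, {
    truth <- sample(0:4, 10000, replace = TRUE)
  })
  dec <- cbind(truth,
               simulate_raters(truth, c(0.7, 0.7), seed = 8))
  fit <- staple_fuse(dec)
  errs <- colMeans(dec != truth)
  expect_lt(mean(fit$labels != truth), min(errs[2:3]))
})

test_that("STAPLE honours unanimity, permutation invariance and priors", {
  withr::with_seed(1, truth <- sample(0:3, 4000, replace = TRUE))
  fit <- staple_fuse(cbind(truth, truth, truth))
  expect_identical(as.integer(fit$labels), as.integer(truth))
  expect_true(all(fit$p >= 1 - 1e-6))
  expect_true(all(fit$q >= 1 - 1e-6))
  dec <- simulate_raters(truth, c(0.9, 0.8, 0.7), codes = 0:3, seed = 3)
  f1 <- staple_fuse(dec)
  f2 <- staple_fuse(dec[, c(3, 1, 2)])
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$p[c(3, 1, 2), ], unname(f2$p), ignore_attr = TRUE)
  # idempotence: fusing the fused map with itself reproduces it
  f3 <- staple_fuse(cbind(f1$labels, f1$labels))
  expect_identical(as.integer(f3$labels), as.integer(f1$labels))
  # a constant rater is clamped, not fatal
  fit_c <- staple_fuse(cbind(truth, truth, rep(0L, length(truth))))
  expect_true(all(fit_c$p[3, ] >= 0.01 & fit_c$p[3, ] <= 0.99))
  expect_error(staple_fuse(cbind(truth)), "2 raters")
  expect_error(staple_fuse(cbind(rep(0L, 10), rep(0L, 10))), "2 distinct")
})

test_that("tidy and glance summarize a STAPLE fit", {
  withr::with_seed(2, truth <- sample(0:2, 2000, replace = TRUE))
  fit <- staple_fuse(simulate_raters(truth, c(0.9, 0.8), codes = 0:2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 2L * 3L)
  gl <- glance(fit)
  expect_identical(gl$raters, 2L)
  expect_true(gl$iterations >= 1)
})

test_that("MAIS with identical atlases equals SAIS and keeps the decision
           geometry", {
  ph <- tiny_phantom()
  w <- random_smooth_deformation(ph$image, amplitude = 2, scale = 18,
                                 seed = 6, compute_inverse = FALSE)
  S <- warp_image(ph$image, w)
  atlases <- rep(list(list(image = ph$image, labels = ph$labels)), 3)
  sais <- segment_single_atlas(S, ph$image, ph$labels, "sdd",
                               config = quick_config())
  mais <- segment_multi_atlas(S, atlases, engine = "sdd",
                              config = quick_config())
  expect_identical(mais$labels, sais$labels)
  per <- attr(mais, "per_atlas")
  expect_length(per, 3)
  expect_identical(dim(per[[1]]$labels), dim(S$values))
  expect_error(segment_multi_atlas(S, atlases[1]), "at least 2")
})

test_that("majority vote fuses ties toward the lowest code", {
  dec <- cbind(c(1L, 2L, 0L, 3L), c(2L, 2L, 4L, 3L), c(3L, 1L, 4L, 0L))
  fused <- fuse_majority(dec)
  expect_identical(fused, c(1L, 2L, 4L, 3L))
})

test_that("threshold baseline reproduces clean phantom tissue bands", {
  ph <- generate_phantom(phantom_spec(site = 66, seed = 4, image_size = 128))
  pred <- segment_threshold(ph$image)
  sc <- score_segmentation(pred, ph$labels)
  # density bands overlap, so this baseline is imperfect by design
  expect_true(all(sc$dsc > 0.3))
  expect_true(sc$dsc[sc$tissue == "cortical"] > 0.8)
  expect_error(segment_threshold(ph$image, cuts = c(5, 2, 10, 20)),
               "increasing")
})
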