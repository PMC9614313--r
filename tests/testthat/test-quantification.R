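# Tissue CSA/density computation, CV-RMSD, and age-trend regression.

test_that("CSA is pixel count times squared spacing and partitions the
           image", {
  lab <- labelmap2d(matrix(c(rep(3L, 400), rep(0L, 624)), 32, 32),
                    spacing = 0.5)
  expect_equal(tissue_csa(lab, "muscle"), 400 * 0.25)
  expect_equal(tissue_csa(lab, "sat"), 0)
  total <- sum(vapply(0:4, function(tc) tissue_csa(lab, tc), numeric(1)))
  expect_equal(total, 32 * 32 * 0.25)
  expect_error(tissue_csa(lab, 9), "invalid")
})

test_that("tissue density is the arithmetic mean over tissue pixels", {
  lab <- labelmap2d(matrix(c(rep(1L, 2), rep(0L, 62)), 8, 8), spacing = 0.5)
  img <- raster2d(matrix(300, 8, 8), spacing = 0.5)
  expect_equal(tissue_density(img, lab, "trabecular"), 300)
  img2 <- raster2d(matrix(c(100, 200, rep(0, 62)), 8, 8), spacing = 0.5)
  expect_equal(tissue_density(img2, lab, 1), 150)
  expect_true(is.na(tissue_density(img, lab, "sat")))
  # phantom: recovered mean within 2 SE of the generator's tissue mean
  ph <- generate_phantom(phantom_spec(site = 66, seed = 13,
                                      image_size = 128, pv_blur = 0))
  tp <- default_tissue_params()
  for (ts in c("muscle", "sat")) {
    n_px <- sum(ph$labels$labels == tissue_codes[[ts]])
    se <- tp$sds[[ts]] / sqrt(n_px)
    expect_lt(abs(tissue_density(ph$image, ph$labels, ts) - tp$means[[ts]]),
              2 * se + 1e-9)
  }
})

test_that("CV-RMSD matches its closed form and is scale invariant", {
  expect_equal(cv_rmsd(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(cv_rmsd(c(1, 1), c(0, 2)), 1)
  y <- c(2, 4, 9); yh <- c(2.5, 3.5, 8)
  expect_equal(cv_rmsd(3 * y, 3 * yh), cv_rmsd(y, yh))
  expect_error(cv_rmsd(c(-1, 1), c(0, 0)), "undefined")
  expect_error(cv_rmsd(1:3, 1:4), "length")
})

test_that("age regression is exact on a noiseless line and stable under
           permutation", {
  rec <- tibble::tibble(id = sprintf("S%02d", 1:20), age = 31:50,
                        sex = rep(c("male", "female"), 10),
                        tissue = "muscle", csa_mm2 = 2 * (31:50) + 5)
  # lm warns about the summary of an exactly perfect fit; that is the point
  fit <- suppressWarnings(regress_age(rec, "csa_mm2", strata = "total"))
  expect_equal(fit$results$slope, 2)
  expect_equal(fit$results$intercept, 5)
  expect_equal(fit$results$r_squared, 1)
  expect_equal(fit$results$cv_rmsd, 0, tolerance = 1e-10)
  perm <- suppressWarnings(
    regress_age(rec[sample(20), ], "csa_mm2", strata = "total"))
  expect_equal(perm$results, fit$results)
  expect_error(regress_age(rec[1:2, ], "csa_mm2", strata = "total"),
               "fewer than 3")
  rec$age <- 40
  expect_error(regress_age(rec, "csa_mm2", strata = "total"),
               "age variance")
})

test_that("tidy, glance and autoplot summarize age-trend fits", {
  withr::with_seed(5, {
    rec <- tibble::tibble(id = sprintf("S%03d", 1:60),
                          age = round(runif(60, 30, 90)),
                          sex = rep(c("male", "female"), 30),
                          tissue = "muscle",
                          csa_mm2 = 900 - 4 * round(runif(60, 30, 90)))
  })
  rec$csa_mm2 <- 900 - 4 * rec$age + rnorm(60, 0, 10)
  fit <- regress_age(rec, "csa_mm2")
  td <- tidy(fit)
  expect_identical(td$stratum, c("total", "male", "female"))
  gl <- glance(fit)
  expect_identical(gl$n, 60L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("sex-stratified fits have lower CV-RMSD than pooled on cohorts
           with sex-offset means", {
  coh <- generate_cohort(120, seed = 14, image_size = 64,
                         sex_effects = list(muscle_csa = 60,
                                            muscle_density = 3))
  q <- quantify_cohort(coh)
  fit <- regress_age(q, "csa_mm2", tissue = "muscle")
  res <- fit$results
  pooled <- res$cv_rmsd[res$stratum == "total"]
  expect_lt(res$cv_rmsd[res$stratum == "male"], pooled)
  expect_lt(res$cv_rmsd[res$stratum == "female"], pooled)
})

test_that("generator trends are recovered with the configured sign", {
  coh <- generate_cohort(120, seed = 15, image_size = 128)
  q <- quantify_cohort(coh)
  tr <- default_trend_params()
  for (ck in list(c("muscle", "csa_mm2", "muscle_csa"),
                  c("cortical", "csa_mm2", "cortical_csa"),
                  c("trabecular", "density", "trabecular_density"),
                  c("cortical", "density", "cortical_density"),
                  c("muscle", "density", "muscle_density"))) {
    fit <- regress_age(q, ck[2], tissue = ck[1], strata = "total")
    expect_equal(sign(fit$results$slope), sign(tr[[ck[3]]]),
                 info = ck[3])
  }
})
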