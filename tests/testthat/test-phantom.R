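# Synthetic phantom generator: determinism, site-tissue sets, intensity
# overlap, motion artifacts, random deformations, cohorts.

test_that("phantom generation is deterministic and site-aware", {
  a <- tiny_phantom(seed = 11)
  b <- tiny_phantom(seed = 11)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_false(identical(tiny_phantom(seed = 12)$image$values,
                         a$image$values))
  # Site-specific tissue sets: 66% has all five codes, 38% bone only,
  # 4% a trabecular epiphysis
  expect_setequal(unique(as.vector(a$labels$labels)), 0:4)
  l38 <- tiny_phantom(seed = 2, site = 38)$labels
  expect_setequal(unique(as.vector(l38$labels)), 0:2)
  l4 <- tiny_phantom(seed = 2, site = 4)$labels
  expect_setequal(unique(as.vector(l4$labels)), 0:1)
  expect_error(phantom_spec(site = 50), "site")
  expect_error(phantom_spec(motion_grade = 6), "motion_grade")
})

test_that("SAT and muscle intensity distributions overlap substantially", {
  ph <- generate_phantom(phantom_spec(site = 66, seed = 5, image_size = 128))
  sat <- ph$image$values[ph$labels$labels == tissue_codes[["sat"]]]
  mus <- ph$image$values[ph$labels$labels == tissue_codes[["muscle"]]]
  brk <- seq(min(sat, mus), max(sat, mus), length.out = 40)
  hs <- hist(sat, breaks = brk, plot = FALSE)$density
  hm <- hist(mus, breaks = brk, plot = FALSE)$density
  ovl <- sum(pmin(hs, hm)) * diff(brk[1:2])
  expect_gt(ovl, 0.05)
})

test_that("motion artifacts scale with grade and stay inside the leg", {
  ph <- tiny_phantom(seed = 21)
  expect_identical(apply_motion_artifact(ph$image, ph$labels, 1)$values,
                   ph$image$values)
  expect_error(apply_motion_artifact(ph$image, ph$labels, 0), "grade")
  pert <- vapply(2:5, function(g) {
    out <- apply_motion_artifact(ph$image, ph$labels, g, seed = 7)
    d <- abs(out$values - ph$image$values)
    # zero outside the leg
    expect_equal(max(d[ph$labels$labels == 0L]), 0)
    mean(d[ph$labels$labels == tissue_codes[["muscle"]]])
  }, numeric(1))
  expect_true(all(diff(pert) > 0))        # monotone in grade (fixed seed)
  # determinism
  o1 <- apply_motion_artifact(ph$image, ph$labels, 4, seed = 9)
  o2 <- apply_motion_artifact(ph$image, ph$labels, 4, seed = 9)
  expect_identical(o1$values, o2$values)
})

test_that("random smooth deformations are bounded, invertible, smooth", {
  img <- tiny_phantom()$image
  z <- random_smooth_deformation(img, amplitude = 0, seed = 1)
  expect_equal(max(abs(z$dx)), 0)
  expect_equal(max(abs(z$dy)), 0)
  for (seed in 1:4) {
    f <- random_smooth_deformation(img, amplitude = 3, scale = 20,
                                   seed = seed)
    expect_lte(max(sqrt(f$dx^2 + f$dy^2)), 3 + 1e-9)
    expect_gt(min(jacobian_det(f)), 0)
    expect_lt(field_inverse_residual(f), 0.1)   # mean residual < 0.1 px
  }
  expect_error(random_smooth_deformation(img, amplitude = -1), "amplitude")
})

test_that("cohort generation is reproducible with age-structured records", {
  a <- generate_cohort(5, seed = 31, image_size = 64)
  b <- generate_cohort(5, seed = 31, image_size = 64)
  expect_identical(a$id, b$id)
  expect_identical(a$age, b$age)
  expect_identical(a$image[[3]]$values, b$image[[3]]$values)
  expect_true(all(a$age >= 26 & a$age <= 104))
  expect_true(all(a$sex %in% c("male", "female")))
})

test_that("configured muscle-CSA decline shows up as negative correlation", {
  coh <- generate_cohort(60, seed = 32, image_size = 128)
  q <- quantify_cohort(coh)
  mus <- q[q$tissue == "muscle", ]
  expect_lt(cor(mus$csa_mm2, mus$age), 0)
})

test_that("null trends produce no significant age slopes", {
  zero <- list(trabecular_density = 0, cortical_density = 0,
               muscle_density = 0, sat_density = 0, trabecular_csa = 0,
               cortical_csa = 0, muscle_csa = 0, sat_csa = 0)
  coh <- generate_cohort(200, seed = 33, image_size = 64,
                         trend_params = zero,
                         sex_effects = list(muscle_csa = 0,
                                            muscle_density = 0))
  q <- quantify_cohort(coh)
  for (ts in c("muscle", "sat")) {
    fit <- regress_age(q, "csa_mm2", tissue = ts, strata = "total")
    expect_gt(fit$results$p_value, 0.01)
  }
})
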