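# Synthetic pQCT-like lower-leg phantom generator.  Stands in for private
# clinical scans: nested-tissue leg geometry at the 4/38/66% tibial sites,
# overlapping tissue intensity distributions, smooth inter-subject
# deformations, graded motion artifacts, and age-structured cohorts with
# known composition trends.

#' Phantom specification
#'
#' Collects the parameters of a single synthetic lower-leg cross-section.
#' Which tissues exist depends on the site: 4% is a trabecular-dominant
#' epiphysis, 38% a cortical ring around a trabecular core (plus fibula),
#' 66% the full nested set SAT > muscle > tibia (cortical ring, trabecular
#' core) with a fibula companion bone.
#'
#' @param site tibial site, one of 4, 38, 66 (% tibial length).
#' @param seed integer RNG seed; the phantom is bit-reproducible given it.
#' @param image_size image width/height in pixels (default 128).
#' @param spacing pixel spacing in mm (default 0.5).
#' @param tissue_params list with numeric vectors `means` and `sds`, named
#'   air/trabecular/cortical/muscle/sat, giving per-tissue intensity
#'   distributions (calibrated density units).
#' @param geometry_jitter standard deviation of the low-order radial Fourier
#'   shape perturbation (relative units).
#' @param motion_grade integer 1-5 motion-artifact severity (1 = none).
#' @param areas optional named list overriding target cross-sectional areas
#'   in mm^2 (`trabecular`, `cortical`, `muscle`, `sat` as present at the
#'   site); defaults scale with the field of view.
#' @param pv_blur partial-volume blur of the tissue mean map at boundaries,
#'   in pixels (default 0.7; 0 keeps per-tissue means exact, so cohort
#'   quantification has bias-free ground truth).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(site = 66, seed = 1L, image_size = 128L,
                         spacing = 0.5, tissue_params = NULL,
                         geometry_jitter = 0.03, motion_grade = 1L,
                         areas = NULL, pv_blur = 0.7) {
  if (!site %in% c(4, 38, 66)) stop("site must be one of 4, 38, 66")
  if (!motion_grade %in% 1:5) stop("motion_grade must be an integer in 1..5")
  tp <- modifyList(default_tissue_params(), tissue_params %||% list())
  if (any(tp$sds < 0)) stop("tissue sds must be >= 0")
  a <- modifyList(.default_areas(site, image_size, spacing),
                  areas %||% list())
  structure(list(site = site, seed = as.integer(seed),
                 image_size = as.integer(image_size), spacing = spacing,
                 tissue_params = tp, geometry_jitter = geometry_jitter,
                 motion_grade = as.integer(motion_grade), areas = a,
                 pv_blur = pv_blur),
            class = "phantom_spec")
}

#' Default tissue intensity parameters
#'
#' Simulator parameters (not clinical claims): per-tissue intensity means
#' and standard deviations chosen to reproduce the ordering and substantial
#' overlap of soft-tissue density distributions seen in calibrated pQCT.
#' @return list with `means` and `sds` named vectors.
#' @export
default_tissue_params <- function() {
  list(means = c(air = 0, trabecular = 300, cortical = 1100,
                 muscle = 80, sat = 50),
       sds = c(air = 8, trabecular = 60, cortical = 80,
               muscle = 20, sat = 25))
}

# Target tissue areas (mm^2), scaled to the field of view; reference values
# are set for a 64 mm field (128 px at 0.5 mm).
.default_areas <- function(site, image_size, spacing) {
  s <- (image_size * spacing / 64)^2
  switch(as.character(site),
         "4"  = list(trabecular = 450 * s, cortical = 0, muscle = 0, sat = 0),
         "38" = list(trabecular = 60 * s, cortical = 160 * s,
                     muscle = 0, sat = 0),
         "66" = list(trabecular = 140 * s, cortical = 110 * s,
                     muscle = 1100 * s, sat = 450 * s))
}

# Elliptical blob with low-order radial Fourier jitter.  Returns a logical
# mask over physical coordinate matrices X, Y (mm).
.blob_mask <- function(X, Y, center, radius, ax, ay, four) {
  xr <- (X - center[1]) / ax
  yr <- (Y - center[2]) / ay
  r <- sqrt(xr^2 + yr^2)
  th <- atan2(yr, xr)
  rad <- radius
  if (length(four$amp)) {
    mod <- rep(1, length(th))
    for (k in seq_along(four$amp))
      mod <- mod + four$amp[k] * cos((k + 1) * th + four$phase[k])
    rad <- radius * mod
  }
  matrix(r <= rad, nrow(X), ncol(X))
}

.rand_fourier <- function(jitter, n = 3L) {
  list(amp = rnorm(n, 0, jitter), phase = runif(n, 0, 2 * pi))
}

#' Generate a synthetic pQCT cross-section with ground-truth labels
#'
#' Renders the nested leg geometry of the requested site, draws per-pixel
#' tissue intensities from overlapping unimodal (Gaussian) distributions,
#' applies a slight partial-volume blur at tissue boundaries, and adds
#' motion artifacts if `spec$motion_grade > 1`.  Deterministic given
#' `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([raster2d()]), `labels`
#'   ([labelmap2d()]), and `truth` (named list of target per-tissue CSA in
#'   mm^2 and mean density).
#' @export
generate_phantom <- function(spec) {
  withr::with_seed(spec$seed, .render_phantom(spec))
}

.render_phantom <- function(spec) {
  n <- spec$image_size
  sp <- spec$spacing
  half <- (n - 1) * sp / 2
  x <- seq(0, (n - 1) * sp, by = sp) - half
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  a <- spec$areas
  jit <- spec$geometry_jitter
  lab <- matrix(0L, n, n)

  ax <- 1 + rnorm(1, 0, jit / 2); ay <- 1 + rnorm(1, 0, jit / 2)
  eff <- ax * ay
  rad <- function(area) sqrt(area / (pi * eff))   # exact-area radius

  if (spec$site == 4) {
    # trabecular-dominant epiphysis: one big TB blob
    tb <- .blob_mask(X, Y, c(0, 0), rad(a$trabecular), ax, ay,
                     .rand_fourier(jit))
    lab[tb] <- tissue_codes[["trabecular"]]
  } else if (spec$site == 38) {
    # diaphysis: thick cortical ring around trabecular core + fibula
    A_out <- a$trabecular + a$cortical
    f_out <- .rand_fourier(jit)
    out <- .blob_mask(X, Y, c(0, 0), rad(A_out), ax, ay, f_out)
    core <- .blob_mask(X, Y, c(0, 0), rad(a$trabecular), ax, ay, f_out)
    lab[out] <- tissue_codes[["cortical"]]
    lab[core] <- tissue_codes[["trabecular"]]
    fib_c <- c(-0.9, -0.6) * rad(A_out) * 1.8
    A_fib <- 0.16 * A_out
    fo <- .blob_mask(X, Y, fib_c, rad(A_fib), ax, ay, .rand_fourier(jit))
    fi <- .blob_mask(X, Y, fib_c, rad(0.45 * A_fib), ax, ay,
                     .rand_fourier(jit))
    lab[fo] <- tissue_codes[["cortical"]]
    lab[fi] <- tissue_codes[["trabecular"]]
  } else {
    # 66%: SAT ring > muscle > tibia (CB ring, TB core) + fibula
    A_fib <- 40 * (n * sp / 64)^2
    A_tib_out <- a$trabecular + a$cortical
    A_disc <- a$muscle + A_tib_out + A_fib          # muscle compartment disc
    A_leg <- A_disc + a$sat
    R_leg <- rad(A_leg); R_musc <- rad(A_disc); R_tib <- rad(A_tib_out)
    # bone placement is anchored to the site's base geometry so it does not
    # drift with subject-specific (e.g. age-trended) compartment areas
    base0 <- .default_areas(spec$site, n, sp)
    R_musc0 <- rad(base0$muscle + base0$trabecular + base0$cortical + A_fib)
    leg <- .blob_mask(X, Y, c(0, 0), R_leg, ax, ay, .rand_fourier(jit))
    mus <- .blob_mask(X, Y, c(0, 0), R_musc, ax, ay, .rand_fourier(jit))
    f_tib <- .rand_fourier(jit / 2)
    tib_c <- c(0.38, 0.10) * R_musc0
    tibo <- .blob_mask(X, Y, tib_c, R_tib, ax, ay, f_tib)
    tibi <- .blob_mask(X, Y, tib_c, rad(a$trabecular), ax, ay, f_tib)
    fib_c <- c(-0.52, -0.38) * R_musc0
    f_fib <- .rand_fourier(jit / 2)
    fibo <- .blob_mask(X, Y, fib_c, rad(A_fib), ax, ay, f_fib)
    fibi <- .blob_mask(X, Y, fib_c, rad(0.4 * A_fib), ax, ay, f_fib)
    lab[leg] <- tissue_codes[["sat"]]
    lab[mus] <- tissue_codes[["muscle"]]
    lab[tibo | fibo] <- tissue_codes[["cortical"]]
    lab[tibi | fibi] <- tissue_codes[["trabecular"]]
  }

  means <- spec$tissue_params$means
  sds <- spec$tissue_params$sds
  ord <- c("air", "trabecular", "cortical", "muscle", "sat")
  base <- matrix(means[ord][lab + 1L], n, n)
  if (spec$pv_blur > 0)
    base <- cpp_gauss_blur(base, spec$pv_blur)    # partial-volume edges
  noise <- matrix(rnorm(n * n, 0, 1), n, n) * matrix(sds[ord][lab + 1L], n, n)
  img <- raster2d(base + noise, spacing = sp)
  labels <- labelmap2d(lab, spacing = sp)

  if (spec$motion_grade > 1L)
    img <- apply_motion_artifact(img, labels, spec$motion_grade,
                                 seed = spec$seed + 131071L)

  truth <- list(csa = vapply(ord[-1], function(tn) a[[tn]] %||% 0,
                             numeric(1)),
                density = means[ord[-1]])
  list(image = img, labels = labels, truth = truth)
}

#' Add graded motion artifacts to a phantom
#'
#' Emulates subject-movement degradation: directional streak bands emanating
#' from cortical-bone pixels across the soft tissue, plus a small rigid
#' ghost of the bone contour.  Grade 1 returns the image unchanged; streak
#' count and amplitude grow monotonically with grade 2-5.  The perturbation
#' is confined to the leg (zero in air) and is deterministic given `seed`:
#' the same seed draws one fixed set of candidate streaks, of which higher
#' grades use more, at larger amplitude.
#'
#' @param image a [raster2d()].
#' @param labels the matching [labelmap2d()] (defines bone and leg masks).
#' @param grade integer 1-5.
#' @param seed RNG seed.
#' @return perturbed [raster2d()].
#' @export
apply_motion_artifact <- function(image, labels, grade, seed = 1L) {
  if (!grade %in% 1:5) stop("grade must be an integer in 1..5")
  if (grade == 1L) return(image)
  withr::with_seed(seed, .motion_perturb(image, labels, grade))
}

.motion_perturb <- function(image, labels, grade) {
  lab <- labels$labels
  n_r <- nrow(lab); n_c <- ncol(lab)
  cb <- which(lab == tissue_codes[["cortical"]], arr.ind = TRUE)
  if (nrow(cb) == 0L)
    cb <- which(lab == tissue_codes[["trabecular"]], arr.ind = TRUE)
  leg <- lab != 0L
  cols <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  rows <- matrix(seq_len(n_r), n_r, n_c)

  max_streaks <- 8L
  pick <- cb[sample.int(nrow(cb), max_streaks, replace = TRUE), , drop = FALSE]
  angles <- runif(max_streaks, 0, pi)
  widths <- runif(max_streaks, 1, 2.5)
  signs <- sample(c(-1, 1), max_streaks, replace = TRUE)
  ghost_dir <- runif(1, 0, 2 * pi)

  n_streaks <- 2L * (grade - 1L)
  amp <- 14 * (grade - 1)
  pert <- matrix(0, n_r, n_c)
  for (s in seq_len(n_streaks)) {
    d <- (cols - pick[s, 2]) * sin(angles[s]) -
         (rows - pick[s, 1]) * cos(angles[s])
    pert <- pert + signs[s] * amp * exp(-d^2 / (2 * widths[s]^2))
  }
  # rigid ghost of the bone compartment, 1-4 px offset scaled by grade
  shift_px <- grade - 1L
  bone <- image$values * (lab %in% c(1L, 2L))
  dim(bone) <- dim(lab)
  sx <- as.vector(cols) - 1 - shift_px * cos(ghost_dir)
  sy <- as.vector(rows) - 1 - shift_px * sin(ghost_dir)
  ghost <- matrix(cpp_sample_bilinear(bone, sx, sy, 0), n_r, n_c)
  pert <- pert + 0.05 * (grade - 1) * ghost
  pert[!leg] <- 0
  raster2d(image$values + pert, spacing = image$spacing,
           origin = image$origin)
}

#' Random smooth invertible deformation field
#'
#' Band-limited Gaussian random field: white noise per component smoothed at
#' the requested correlation scale, rescaled so the largest displacement
#' equals `amplitude`, then shrunk if needed until the Jacobian determinant
#' stays positive.  The inverse (fixed-point iteration) is stored on the
#' result.  Provides known ground-truth warps for registration recovery
#' experiments.
#'
#' @param ref a [raster2d()] (or [labelmap2d()]) defining the target grid.
#' @param amplitude maximum displacement magnitude in mm (>= 0).
#' @param scale correlation length in mm.
#' @param seed RNG seed.
#' @param compute_inverse store the numerical inverse (default TRUE).
#' @return a [dispfield2d()].
#' @export
random_smooth_deformation <- function(ref, amplitude = 3, scale = 20,
                                      seed = 1L, compute_inverse = TRUE) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  d <- dim(ref)
  if (amplitude == 0)
    return(dispfield2d(matrix(0, d[1], d[2]), matrix(0, d[1], d[2]),
                       spacing = ref$spacing, origin = ref$origin,
                       inverse = list(dx = matrix(0, d[1], d[2]),
                                      dy = matrix(0, d[1], d[2]))))
  withr::with_seed(seed, {
    sig <- scale / ref$spacing / 2
    dx <- cpp_gauss_blur(matrix(rnorm(prod(d)), d[1], d[2]), sig)
    dy <- cpp_gauss_blur(matrix(rnorm(prod(d)), d[1], d[2]), sig)
    m <- max(sqrt(dx^2 + dy^2))
    dx <- dx * amplitude / m
    dy <- dy * amplitude / m
    u <- dispfield2d(dx, dy, spacing = ref$spacing, origin = ref$origin)
    while (min(jacobian_det(u)) <= 0.05) {
      u <- dispfield2d(u$dx * 0.7, u$dy * 0.7,
                       spacing = ref$spacing, origin = ref$origin)
    }
    if (compute_inverse) {
      inv <- invert_field(u)
      u$inverse <- list(dx = inv$dx, dy = inv$dy)
    }
    u
  })
}

#' Generate an age-structured synthetic cohort
#'
#' Draws ages from a truncated normal (mean 69, sd 14.5, range 26-104 years,
#' emulating an aging-cohort age structure), assigns sexes, and renders one
#' phantom per subject whose tissue areas and density means vary linearly
#' with age according to `trend_params` (slopes per year, evaluated around a
#' reference age of 65).  Optional sex offsets shift tissue properties
#' between males and females.  Each subject is additionally warped by a
#' random smooth deformation so cohort geometry varies beyond shape jitter.
#' Downstream regressions therefore have known ground-truth slopes.
#'
#' @param n number of subjects (>= 1).
#' @param site tibial site (default 66).
#' @param seed cohort RNG seed.
#' @param trend_params named list of slopes per year:
#'   `trabecular_density`, `cortical_density`, `muscle_density`
#'   (density units/yr), `trabecular_csa`, `cortical_csa`, `muscle_csa`,
#'   `sat_csa` (mm^2/yr).  Defaults follow the age trends this simulator
#'   emulates, at phantom scale: declining trabecular/cortical/muscle
#'   density and cortical/muscle CSA, flat SAT and trabecular CSA.
#' @param sex_effects named list of additive male-minus-female offsets
#'   applied half positive to males, half negative to females (same names
#'   as `trend_params`).
#' @param image_size,spacing phantom grid parameters.
#' @param grade_probs probabilities of motion grades 1-5 (default: all
#'   grade 1, i.e. no artifacts).
#' @param warp_amplitude amplitude (mm) of the per-subject random smooth
#'   deformation.
#' @param pv_blur partial-volume blur passed to [phantom_spec()]; the
#'   cohort default is 0 so that measured per-tissue CSA and density are
#'   unbiased for the configured targets (no boundary mixing), which makes
#'   the generator's trend slopes exactly recoverable by regression.
#' @return tibble with columns `id`, `age`, `sex`, `site`, `motion_grade`,
#'   list-columns `image`, `labels`, and `truth` (per-subject target CSA and
#'   density values).
#' @export
generate_cohort <- function(n, site = 66, seed = 1L, trend_params = NULL,
                            sex_effects = NULL, image_size = 128L,
                            spacing = 0.5, grade_probs = c(1, 0, 0, 0, 0),
                            warp_amplitude = 1.5, pv_blur = 0) {
  stopifnot(n >= 1)
  tr <- modifyList(default_trend_params(), trend_params %||% list())
  sx <- modifyList(list(muscle_csa = 120, muscle_density = 3),
                   sex_effects %||% list())
  withr::with_seed(seed, {
    age <- round(pmin(104, pmax(26, rnorm(n, 69, 14.5))))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    grade <- sample(1:5, n, replace = TRUE, prob = grade_probs)
    sub_seeds <- sample.int(2^30, n)
  })
  base <- .default_areas(site, image_size, spacing)
  tp0 <- default_tissue_params()
  ref_age <- 65

  recs <- purrr::map(seq_len(n), function(i) {
    da <- age[i] - ref_age
    sgn <- if (sex[i] == "male") 0.5 else -0.5
    off <- function(name) (tr[[name]] %||% 0) * da +
      sgn * (sx[[name]] %||% 0)
    areas <- list(
      trabecular = max(base$trabecular + off("trabecular_csa"), 1),
      cortical = if (base$cortical > 0)
        max(base$cortical + off("cortical_csa"), 1) else 0,
      muscle = if (base$muscle > 0)
        max(base$muscle + off("muscle_csa"), 10) else 0,
      sat = if (base$sat > 0) max(base$sat + off("sat_csa"), 10) else 0)
    means <- tp0$means
    means[["trabecular"]] <- means[["trabecular"]] + off("trabecular_density")
    means[["cortical"]] <- means[["cortical"]] + off("cortical_density")
    means[["muscle"]] <- means[["muscle"]] + off("muscle_density")
    means[["sat"]] <- means[["sat"]] + off("sat_density")
    spec <- phantom_spec(site = site, seed = sub_seeds[i],
                         image_size = image_size, spacing = spacing,
                         tissue_params = list(means = means),
                         motion_grade = grade[i], areas = areas,
                         pv_blur = pv_blur)
    ph <- generate_phantom(spec)
    if (warp_amplitude > 0) {
      w <- random_smooth_deformation(ph$image, amplitude = warp_amplitude,
                                     scale = 18, seed = sub_seeds[i] + 1L,
                                     compute_inverse = FALSE)
      ph$image <- warp_image(ph$image, w)
      ph$labels <- warp_labels(ph$labels, w)
    }
    list(image = ph$image, labels = ph$labels,
         truth = list(csa = areas, density = as.list(means)))
  })

  tibble::tibble(
    id = sprintf("S%03d", seq_len(n)), age = age, sex = sex, site = site,
    motion_grade = grade,
    image = purrr::map(recs, "image"),
    labels = purrr::map(recs, "labels"),
    truth = purrr::map(recs, "truth"))
}

#' Default age-trend slopes for the cohort generator
#'
#' Density slopes (units per year) are set at calibrated-density scale;
#' CSA slopes are set at the phantom's miniature-leg scale (mm^2 per year).
#' Trabecular and SAT CSA and SAT density default to zero (no trend).
#' @return named list of slopes.
#' @export
default_trend_params <- function() {
  list(trabecular_density = -1.603, cortical_density = -1.784,
       muscle_density = -0.127, sat_density = 0,
       trabecular_csa = 0, cortical_csa = -0.3,
       muscle_csa = -5, sat_csa = 0)
}
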