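---
title: "Multi-atlas segmentation and quantification of lower-leg pQCT cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas segmentation and quantification of lower-leg pQCT cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(pqctseg)
```

## The problem

Peripheral quantitative computed tomography (pQCT) produces
density-calibrated 2-D cross-sections of the lower leg at standard sites
(4%, 38% and 66% of tibial length).  Quantifying trabecular bone, cortical
bone, muscle and subcutaneous adipose tissue (SAT) in these slices is the
basis of body-composition studies of aging, but two properties of the
modality defeat density-only segmentation: the intensity distributions of
the soft tissues overlap heavily, and involuntary subject movement imprints
streaks and ghosting whose severity is conventionally graded 1 (none) to 5
(severe).

`pqctseg` implements a multi-atlas image segmentation (MAIS) pipeline for
this setting: labeled template scans ("atlases") are warped onto the
subject by affine plus deformable registration, their label maps are
propagated through the estimated transforms, and the competing propagated
segmentations are fused into a consensus by the STAPLE
expectation-maximization algorithm.  Because no public pQCT cohort with
reference masks exists, the package also ships a synthetic phantom
generator that emulates the relevant properties of such scans; every claim
the test suite makes is a claim about performance on those phantoms.

## Registration model

All registrations estimate *pull-back* transforms: a transform maps
subject (fixed-grid) coordinates into atlas (moving) coordinates, so the
atlas is resampled in a single pass.  Pixels are addressed 0-based with
pixel-center sampling at `x = col * spacing + origin`; displacement fields
are stored in millimetres on the fixed grid.  Points mapped outside the
source field of view take the background value 0 (air).

### Energy

Deformable registration minimizes

    E(tau) = lambda_sim * MI(S, A o tau) + lambda_reg * rho(tau)

with `lambda_sim = -1` and `lambda_reg = 0.01` by default, i.e. mutual
information is maximized under a bending-energy penalty.  (Written with the
similarity defined as *negative* MI and a weight of -1, the printed energy
would be maximized-badness; the implementation keeps the evident intent
and `mattes_mi()` itself returns the negative-MI convention, which is what
its sign tests assert.)

### Mattes mutual information

`mattes_mi()` builds a joint histogram with 32 bins per axis (configurable;
at least 8) using first-order linear Parzen windows on both axes — each
sample spreads bilinearly over the four neighbouring joint-histogram cells.
This smooths the histogram and makes MI differentiable in the moving
intensities, which the FFD gradient uses.  A constant image has zero
marginal entropy; MI is defined as 0 there and flagged.  Bin edges adapt to
each image's range, so the measure is invariant to affine intensity
rescaling and symmetric in its arguments.

### Affine stage

`register_affine()` is a regular step gradient descent on the six affine
parameters (linear part expressed as a deviation from the identity scaled
by the half field extent, so all parameters live on a comparable mm scale),
with central finite-difference gradients (step 0.3 in scaled units — small
steps produced noticeably noisier MI gradients and stalled rotation
recovery), step halving on any non-improving trial, two resolution levels,
and intensity-centroid initialization.  On 64 px phantoms it recovers
translations to well under half a pixel and 10 degree rotations to about
0.1 degree in roughly a second.

### B-spline free-form deformation

The FFD warp is a tensor product of 1-D cubic B-splines on a uniform
control lattice padded one cell beyond the image.  Two conventions in the
printed formulation are treated as typos, as the mathematics demands:

* the tensor-product sum runs over the full 4x4 cubic support (a 3x3 sum
  breaks the partition of unity, which the tests assert to 1e-12);
* the "thin-plate bending energy" regularizer is implemented in its
  standard second-order form, the domain-normalized integral of
  `t_xx^2 + 2 t_xy^2 + t_yy^2` over both components (a squared sum of
  first derivatives, as printed, is not a bending energy: it fails to
  vanish on affine — e.g. rigid — fields, which the zero-on-affine test
  pins down).

Optimization is L-BFGS-B with the analytic gradient assembled by the chain
rule: the per-pixel MI derivative with respect to the warped intensity,
times the warped image's spatial gradient, scattered onto the lattice
through the B-spline weights; the bending term's gradient uses the same
scatter machinery with second-derivative bases.  Two levels are used
(control spacing 16 px then 8 px, the coarse solution seeding the fine
lattice).

### Log-domain symmetric diffeomorphic demons

The transform is maintained as the exponential of a stationary velocity
field, computed by scaling and squaring with the scaling power chosen so
the scaled field stays below half a pixel; the inverse is `exp(-v)`.  Each
iteration computes the forward force from `(S, A o tau)` and the backward
force from `(A, S o tau^{-1})`, averages them antisymmetrically, smooths
the update with a fluid-like Gaussian (sigma 2 px), composes it into the
velocity at first BCH order (`v <- v + eps * u`, `eps = 1`), and smooths
the velocity with an elastic-like Gaussian (sigma 1 px).  Three resolution
levels, 50 iterations each; the symmetric mean-squared energy is tracked
and a level stops early (reverting to its best state) after five
non-improving iterations.

The update force is

    u(x) = -(S - M)(x) * J(x) / (||J(x)||^2 + r(x)^2 / lambda_h^2)

with `J` the warped moving image's gradient and `r = S - M`.  The
correspondence-uncertainty term is deliberately kept *per pixel* (the
squared local residual over `lambda_h^2`, default `lambda_h` = one pixel
spacing): this bounds every step by `lambda_h / 2`, makes the update
invariant to global intensity rescaling, and in warp-recovery experiments
reaches Dice >= 0.99 on all tissues, whereas folding the term into a
single constant is intensity-scale dependent and left SAT near 0.88-0.96
depending on the constant.  The single-pixel worked example for the update
(residual 2, unit gradient, ratio 1, giving `u = (-1, 0)`) is asserted
verbatim in the tests.

## Statistical atlas

`build_statistical_atlas()` iterates group averaging: iteration 1 affinely
registers every subject to a chosen reference (default the first) and
averages; iterations 2..K (default K = 5) register each affinely aligned
subject to the current average with the demons engine and re-average.  The
affine stage is not repeated in later iterations.  For averaging, each
original subject is resampled exactly once through the composed
affine-plus-deformable transform — a second interpolation pass measurably
blurred the template — and out-of-view pixels are excluded from the
per-pixel mean.  The mean-squared change between successive templates is
recorded; it decreases from iteration 2 onward on the phantom cohorts and
is logged, not enforced.  Labels reach the atlas by nearest-neighbour
propagation from a labeled reference through the reference-to-atlas
transform.

## STAPLE fusion

The decision matrix holds one propagated label per atlas ("rater") per
pixel.  Rater performance is modeled per class in one-vs-rest form: the
probability that rater k reports class l when the truth is l is `p[k, l]`,
and the residual mass `1 - p[k, l]` is spread uniformly over the other
labels.  This choice makes the E-step a pure Bayes update and the M-step a
closed-form posterior-weighted average — an *exact* EM, so the
observed-data log-likelihood is non-decreasing at every iteration, which
the tests assert on every fit.  Specificity `q[k, l]` is re-estimated from
the posteriors each M-step and reported alongside `p`; in the two-class
case `p[k, 0]` *is* the specificity and the model coincides with binary
STAPLE.  Class priors default to the relative label frequencies across all
raters; initialization is `p = q = 0.9`; convergence at a parameter change
below 1e-5 or 100 iterations; fused labels are posterior arg-max with ties
broken toward the lowest code; a rater whose decision map is constant has
its estimates clamped to [0.01, 0.99].  A full confusion-matrix variant
was considered and rejected as the default because the one-vs-rest form
matches the two-parameter (p, q) reporting convention; majority voting is
available as a baseline (`fuse_majority()`).

The statistical atlas itself can serve as one of the MAIS raters; the
pipeline includes it by default alongside the individual templates.

## The phantom generator

`generate_phantom()` renders a nested-tissue leg cross-section:

* **66%**: skin ellipse > SAT ring > muscle compartment > tibia (cortical
  ring around a trabecular core) plus a fibula companion bone;
* **38%**: a thick cortical ring around a trabecular core, plus fibula
  (bone-only label set);
* **4%**: a trabecular-dominant epiphysis.

Boundaries are ellipses modulated by low-order radial Fourier jitter
(orders 2-4, relative sd 0.03 by default).  Radii are derived from target
areas, so cross-sectional areas are controlled exactly up to pixelation;
bone placement is anchored to the site's *base* geometry so that
age-trended compartment areas do not drag the bones around (an earlier
coupling of bone position to the subject's muscle radius leaked a spurious
age trend of about +0.01 mm^2/yr into measured cortical CSA).

Intensities are drawn per pixel from overlapping Gaussians (air 0±8,
SAT 50±25, muscle 80±20, trabecular 300±60, cortical 1100±80 — simulator
parameters chosen to reproduce the ordering and heavy soft-tissue overlap
of calibrated pQCT, not clinical claims), after an optional partial-volume
blur of the mean map (0.7 px for single phantoms; the cohort generator
defaults to 0 so that measured densities are unbiased for the configured
means and trend slopes are exactly recoverable).

**Motion artifacts** (`apply_motion_artifact()`): grade 1 returns the
image unchanged; grades 2-5 add oriented Gaussian streak bands through
randomly chosen cortical-bone pixels (2(g-1) streaks of amplitude
14(g-1)) plus a rigid bone ghost offset by g-1 px at weight 0.05(g-1),
confined to the leg mask so air is untouched.  One fixed candidate-streak
set is drawn per seed and higher grades use more of it at larger
amplitude, which makes perturbation energy strictly monotone in grade at
fixed seed.  The grade semantics beyond "streaks and ghosting" are a
simulator design choice; no sinogram-domain physics is attempted.

**Cohorts** (`generate_cohort()`): ages from a truncated normal (mean 69,
sd 14.5, range 26-104), random sexes, and per-subject phantoms whose
tissue areas and density means vary linearly with age around a reference
age of 65.  Default slopes at phantom scale: muscle CSA -5 and cortical
CSA -0.3 mm^2/yr (the miniature 64 mm field cannot sustain full-leg
declines of tens of mm^2 per year over 78 years), trabecular, cortical and
muscle density -1.603, -1.784 and -0.127 units/yr (densities live on the
calibrated scale, so these carry over directly), SAT and trabecular CSA
flat.  Sex offsets (default +120 mm^2 muscle CSA, +3 muscle density for
males) give the gender-conditional analyses something to find.  Each
subject is additionally warped by a random smooth deformation
(`random_smooth_deformation()`: band-limited Gaussian random field,
max-normalized, shrunk until the Jacobian determinant stays positive, with
a stored fixed-point inverse).

### What the phantoms do and do not emulate

They emulate: nested anatomy with realistic topology at three sites,
overlapping tissue densities, inter-subject shape variation, smooth
deformations with known ground truth, graded streak/ghost artifacts, and
age-structured composition trends.  They do not emulate: CT reconstruction
physics (beam hardening, ring artifacts, sinogram-consistent motion),
scanner calibration, cortical porosity, or anatomical pathology.  Passing
the bundled experiments therefore demonstrates correctness and robustness
of the *algorithms* under controlled conditions, not clinical performance
on scanner data.

## Evaluation and quantification

`overlap_metrics()` computes Dice, sensitivity (TPR) and precision (PR)
per tissue; empty-denominator cases are reported as missing rather than 0,
because a tissue absent from both maps carries no evidence either way.
`wilcoxon_rank_sum()` delegates to the standard rank-sum machinery: exact
enumeration when the pooled sample has at most 20 observations and no
ties, otherwise the normal approximation with continuity and tie
correction; the degenerate all-equal case returns p = 1.
`motion_stratified_report()` compares grades 1-3 against 4-5 per tissue
and method with stratum means, the relative difference
`(high - low)/low * 100`, and the rank-sum p-value.

`tissue_csa()` is pixel count times squared spacing; `tissue_density()`
the arithmetic mean over tissue pixels (missing when absent).
`regress_age()` fits ordinary least squares of a property on age per
stratum (total/male/female), reporting slope, intercept, R^2, CV-RMSD
(root-mean-squared difference over the observed mean) and the
t-distribution slope p-value.  R^2 defaults to the squared Pearson
correlation with a squared-Spearman option — the source conventions are
internally inconsistent on this point, and Pearson matches the OLS fit
actually reported.  Cross-validation bookkeeping (excluding template
subjects from evaluation) is handled at the manifest level by the
pipeline, which scores only non-template subjects.

## Problem sizes and numerical choices

The bundled experiments run at desk scale, chosen once: identity checks on
64 px phantoms; warp-recovery, fusion-benefit and motion experiments on
128 px phantoms (10, 10 and 6 subjects respectively; 3 atlas templates,
matching the standard template count for this pipeline); slope recovery on
cohorts of n = 200.  Determinism is enforced throughout: every stochastic
input takes an explicit seed, registration uses no stochastic sampling,
and EM/optimizer iteration orders are fixed.  Tie-breaks are deterministic
(lowest label code).  Degenerate inputs are handled explicitly: constant
images in MI (zero, flagged), absent tissues (CSA 0, density missing),
constant STAPLE raters (clamped), zero-amplitude deformations (identity
with identity inverse), all-equal rank-sum samples (p = 1).

## Known limitations

2-D single-slice only; no DICOM or scanner-specific calibration; the SyN
family of registrations is out of scope (the comparisons here cover FFD
and demons); the FFD engine is the slower and less accurate of the two
deformable engines on motion-degraded phantoms, mirroring its relative
standing in this application; the phantom is a geometric emulator, so
absolute performance numbers should not be read as clinical accuracy.
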