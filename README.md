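# pqctseg

Multi-atlas segmentation and quantification of hard and soft tissues in
2-D peripheral quantitative computed tomography (pQCT) cross-sections of
the lower leg.

## What it does

pQCT slices of the lower leg at the 4%, 38% and 66% tibial sites are the
workhorse of body-composition studies of aging, but the tissue density
distributions overlap heavily and subject movement imprints streaks and
ghosting (conventionally graded 1-5), so density-only segmentation is
fragile.  `pqctseg` implements a multi-atlas image segmentation (MAIS)
pipeline for this modality:

1. **Registration** of each labeled template ("atlas") to the subject:
   Mattes mutual-information affine alignment, then a deformable engine —
   hierarchical cubic B-spline free-form deformation (FFD, L-BFGS-B with
   an analytic MI gradient and a thin-plate bending-energy penalty,
   `E = -MI + 0.01 * bending`) or log-domain symmetric diffeomorphic
   demons (SDD, velocity-field exponentials via scaling and squaring, so
   forward and inverse warps come as a pair).
2. **Label propagation** through the composed transform with
   nearest-neighbour interpolation in a single resampling pass.
3. **Label fusion** of the propagated segmentations by STAPLE — an EM
   algorithm that jointly estimates the consensus segmentation and each
   atlas's per-class sensitivity `p` and specificity `q` — or by majority
   vote.
4. **Statistical atlas construction** by iterative group registration and
   averaging, with provenance of the per-iteration template change.
5. **Evaluation**: Dice (DSC), sensitivity (TPR), precision (PR) per
   tissue, Wilcoxon rank-sum tests, and motion-stratified comparisons
   (grades 1-3 vs 4-5).
6. **Quantification**: per-tissue cross-sectional area (CSA, mm^2) and
   mean density, with age-trend regression (slope, R^2, CV-RMSD, p) per
   sex stratum.

Because the clinical cohorts this methodology targets are private, the
package bundles a synthetic phantom generator (`generate_phantom()`,
`generate_cohort()`) producing pQCT-like leg cross-sections with ground
truth labels, known smooth deformations, graded motion artifacts, and
age-structured composition trends.  All bundled experiments and tests run
against these phantoms; the methods vignette
(`vignettes/multi-atlas-pqct-segmentation.Rmd`) documents the models, the
defaults and what the phantoms do and do not emulate.

Tissue codes are fixed: 0 air, 1 trabecular bone, 2 cortical bone,
3 muscle, 4 subcutaneous adipose tissue (SAT).  Images travel as NIfTI
(`.nii`/`.nii.gz`) or 16-bit PNG with a JSON sidecar carrying spacing,
origin and calibration.

## A worked example

```r
library(pqctseg)

# three atlas templates and one subject, all synthetic 66%-site phantoms
atl <- generate_cohort(3, site = 66, seed = 77, image_size = 128)
atlases <- lapply(1:3, function(i)
  list(image = atl$image[[i]], labels = atl$labels[[i]]))

sub <- generate_cohort(1, site = 66, seed = 78, image_size = 128)
subject <- sub$image[[1]]
truth   <- sub$labels[[1]]

seg <- segment_multi_atlas(subject, atlases, engine = "sdd",
                           fusion = "staple")
score_segmentation(seg, truth)
#> # A tibble: 4 x 4
#>   tissue       dsc   tpr    pr
#>   <chr>      <dbl> <dbl> <dbl>
#> 1 trabecular 0.977 0.987 0.967
#> 2 cortical   0.941 0.917 0.965
#> 3 muscle     0.965 0.966 0.964
#> 4 sat        0.904 0.920 0.888
```

Each row scores one tissue of the fused segmentation against the phantom's
ground truth: `dsc` is the Dice overlap, `tpr` the fraction of true tissue
recovered, `pr` the fraction of predicted tissue that is correct.  Soft
tissue with the weakest density contrast (SAT) is, as expected, the
hardest.  The STAPLE fit behind the fusion is attached to the result:

```r
glance(attr(seg, "staple"))
#> # A tibble: 1 x 5
#>   raters classes iterations converged log_likelihood
#>    <int>   <int>      <int> <lgl>              <dbl>
#> 1      3       5          7 TRUE             -24271.
```

Quantification and age trends on a cohort:

```r
coh <- generate_cohort(200, seed = 5, image_size = 128)
q <- quantify_cohort(coh)
fit <- regress_age(q, "csa_mm2", tissue = "muscle")
tidy(fit)
#> # A tibble: 3 x 7
#>   stratum slope intercept r_squared cv_rmsd   p_value     n
#>   <chr>   <dbl>     <dbl>     <dbl>   <dbl>     <dbl> <int>
#> 1 total   -5.00     1420.     0.592 0.0557  2.18e- 40   200
#> 2 male    -4.97     1485.     0.999 0.00202 3.42e-129    89
#> 3 female  -5.01     1367.     0.999 0.00189 1.14e-175   111

# autoplot(fit) draws the per-stratum scatter with fitted lines
```

The recovered muscle-CSA slope matches the generator's configured
-5 mm^2/yr, and the sex-stratified fits have lower CV-RMSD than the pooled
fit, as expected for a cohort generated with sex-offset means.

A thin command-line interface with subcommands `simulate`, `build-atlas`,
`segment`, `evaluate`, `quantify` and `run-experiment` is installed at
`inst/cli/pqctseg`.

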