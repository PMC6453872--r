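# radbone

Quantitative subchondral bone analysis from plain knee radiographs:
step-wedge-calibrated bone density, directional fractal signature
texture, group statistics, and elastic-net classification of
osteoarthritis (OA) and bone-marrow-lesion (BML) status.

## The problem

Plain radiographs are cheap and ubiquitous, but two things stand between
their grayscale values and a usable bone biomarker:

1. **Grayscale is not density.** Exposure and vendor post-processing
   (PP) rescale intensities image by image, so the raw mean grayscale of
   a region of interest (GV) does not transfer across images or PP
   modes. Imaging an aluminum step wedge alongside the knee fixes this:
   a third-order polynomial fitted to the mean grayscales of the
   thinnest eight steps maps thickness to grayscale, and inverting it
   converts any ROI's GV into an aluminum-equivalent thickness
   (GV\_mmAl, in mm Al). The thickest steps saturate the detector and
   are never fitted; a GV beyond the fitted curve is excluded rather
   than extrapolated.

2. **Trabecular structure is directional and scale-dependent.** Fractal
   signature analysis (FSA, the blanket method) dilates and erodes the
   image surface with a one-pixel-wide rod element of length *r* = 2..7
   px and measures the inter-blanket volume *V*(*r*). The surface area
   at scale *r* is

   &nbsp;&nbsp;&nbsp;&nbsp;*A*(*r*) = (*V*(*r*) − *V*(*r* − 1)) / 2,

   and the fractal dimension is 2 minus the slope of ln *A*(*r*) versus
   ln *r* — globally from all six points, locally from adjacent pairs,
   reported at the 0.30, 0.44, 0.59 and 0.74 mm scales for 0.148 mm
   pixels. A horizontal rod probes vertical structures (FD\_Ver) and
   vice versa (FD\_Hor). Rough texture gives high FD; for a fractional
   Brownian surface with Hurst exponent *H*, FD ≈ 3 − *H*.

Downstream, groups (control / OA without medial BML / medial BML) are
compared with Shapiro–Wilk-routed ANOVA or Kruskal–Wallis plus post hoc
tests (pooled t or Dunn's z, uncorrected and Bonferroni), and OA/BML
status is classified with elastic-net logistic regression
(α ∈ 0.1..1 step 0.05, λ ∈ 0.001..0.15 step 0.009) tuned by
leave-one-out cross-validation on pooled out-of-fold ROC AUC, with
DeLong 95% confidence intervals.

Because no patient radiographs are distributed, the package ships a
seeded synthetic-cohort generator: fractional-Brownian trabecular
texture with group-dependent density and roughness, an embedded step
wedge with saturated top steps, and a simulated "clinical PP" transform
(sigmoid contrast + unsharp masking). Every stage of the pipeline is
tested against that generator's known ground truth.

## Worked example

```r
library(radbone)

cfg    <- cohort_config(n_per_group = c(4L, 3L, 3L), seed = 7)
cohort <- generate_cohort(cfg)
cohort
#> <radbone_cohort> 10 subjects (groups 4/3/3), 18 ROIs, 720 x 900 px

# calibrate one subject's own step wedge and read off a density
rg    <- cohort$subjects[[1]]$minimal
curve <- fit_wedge_curve(rg$pixels, cfg$wedge)
curve
#> <calibration_curve> gv = 1000 + 900 t + -12 t^2 + 0.04999 t^3  (t in [4, 32] mm)
roi <- cohort$rois[cohort$rois$roi_name == "medial_SB", ]
gv_to_mmal(curve, mean_gv(extract_roi(rg, roi)))
#> # A tibble: 1 x 4
#>       gv gv_mmal excluded exclusion_reason
#>    <dbl>   <dbl> <lgl>    <chr>
#> 1 15335.    21.6 FALSE    <NA>
```

The subject's medial subchondral ROI averages 15335 grayscale units,
which the fitted wedge curve maps to 21.6 mm of aluminum — the
calibrated density that survives a change of post-processing.

```r
fsa_roi(extract_roi(rg, roi), rg$pixel_size_mm, "medial_SB")$vertical
#> <fractal_signature> vertical structures (horizontal element), medial_SB
#>   FD global 2.8238; local [0.30, 0.44, 0.59, 0.74] = 2.8128, 2.8268, 2.8385, 2.7576
```

A global FD of 2.82 for vertical structures is a rough, complex
trabecular texture (the generator drew this subject's Hurst exponent
near 0.3; FD ≈ 3 − H).

```r
feats <- extract_features(cohort, "minimal")
subj  <- unique(cohort$truth[, c("subject_id", "group")])
grp   <- subj$group[match(feats$subject_id, subj$subject_id)]
compare_three_groups(feats$gv_mmal_ROI2, grp)
#> # A tibble: 3 x 5
#>   comparison omnibus_test omnibus_p p_uncorrected p_bonferroni
#> 1 0-1        anova           0.0521        0.0675        0.203
#> 2 0-2        anova           0.0521        0.0523        0.157
#> 3 1-2        anova           0.0521        0.675         1

X  <- as.matrix(feats[, grep("^gv_mmal_|^fd_", names(feats))])
cv <- loocv_grid_search(X, as.integer(grp > 0),
                        enet_config(alpha_grid = c(0.8, 1),
                                    lambda_grid = c(0.037, 0.118)))
cv
#> <enet_cv> selected alpha = 1, lambda = 0.118; pooled LOOCV <roc_result> AUC 0.792 (95% CI 0.448-1.000), 6 pos / 4 neg
```

At n = 10 the medial density effect is only borderline (omnibus
p = 0.052) and the LOOCV AUC of 0.79 carries a wide DeLong interval —
exactly what one should expect from a ten-subject cohort; the reference
study conditions (`cohort_config()` defaults, n = 20/15/10) give stable
group differences and AUCs well above 0.9 (see below). `tidy(cv)`
lists the handful of nonzero coefficients the lasso retained;
`autoplot(cv)` draws the ROC curve, `autoplot(curve)` the wedge fit.

The full pipeline — simulation, features for both PP modes, the group
table, the PP-agreement table, and all four classification models — is
one call: `run_pipeline(cohort_config(seed = 1), out_dir = "results")`.

## Package layout

- `R/fbm.R`, `R/step_wedge.R`, `R/clinical_pp.R`, `R/cohort.R` — synthetic
  radiograph generator (texture, wedge, clinical-PP simulator, cohorts).
- `R/radiograph.R`, `R/roi.R` — 16-bit TIFF/PNG I/O, landmark-driven
  18-ROI layout, ROI extraction.
- `R/calibration.R` — wedge cubic fit, GV → mm Al inversion, exclusion rules.
- `R/fsa.R` — blanket volumes, scale-resolved surface areas,
  global/local FDs.
- `R/stats.R` — normality-routed correlations, three-group comparisons,
  Dunn's test.
- `R/enet.R`, `R/roc.R`, `R/loocv.R`, `R/pipeline.R` — elastic net,
  DeLong ROC, LOOCV grid search, end-to-end orchestration.
- `vignettes/radbone-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, and what the synthetic cohorts do and
  do not establish.
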