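---
title: "Methods: calibrated density and directional fractal texture from knee radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated density and directional fractal texture from knee radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbone)
```

This vignette is the package's own account of its models and the
choices behind them: what each stage assumes, which tunable parameters
matter, what the synthetic-data generator emulates — and therefore what
a green test suite does and does not establish about real radiographs.

## 1. Density calibration with an aluminum step wedge

**Model.** The mean grayscale of a region of interest (GV) is an
exposure- and processing-dependent quantity. A step wedge of known
aluminum thicknesses imaged in the same frame anchors it: the mean
grayscale of each step is measured over a fixed rectangle, a cubic
polynomial is least-squares fitted to (thickness, grayscale) of the
`n_steps_fit = 8` thinnest steps, and an ROI's GV is inverted through
that curve to an aluminum-equivalent thickness, GV~mmAl~ (mm Al). Each
image is calibrated against **its own** wedge, so any monotone
grayscale transform applied to the whole image — including clinical
post-processing — is absorbed by the calibration.

**Assumptions.** The detector response is spatially uniform across the
frame (no heel-effect or scatter correction is attempted), and the
image grayscale is a smooth monotone function of transmitted dose over
the fitted range. The two thickest steps are excluded because a real
detector saturates there; the generator reproduces that saturation so
the exclusion rule is exercised.

**Numerical choices.** Inversion is a dense 0.001 mm grid search over
the fitted range rather than closed-form cubic roots: it is robust to
locally non-monotone fits (flagged via `monotone = FALSE`), and
0.001 mm is far below any biological difference of interest. A GV
above the curve maximum *or* below its minimum is excluded with reason
`"out-of-range"`; the low side is excluded by symmetry of the
no-extrapolation policy even though only the high side occurs in
practice. The fitted-range defaults (10 steps of 4–40 mm, 8 fitted,
saturation between steps 8 and 9) were chosen once so that realistic
subchondral densities (≈ 20–30 mm Al) fall mid-range of the fit.

## 2. Directional fractal signature analysis

**Model.** The image is treated as a surface. Flat grayscale dilation
and erosion with a one-pixel-wide rod of length $r = 2..7$ form upper
and lower blankets; the volume between them, summed over a fixed valid
interior, is $V(r)$, with $V(1) \equiv 0$ because a length-1 flat
element is the identity. The scale-resolved surface area is
$A(r) = (V(r) - V(r-1))/2$, the global fractal dimension is
$2 - \mathrm{slope}$ of the least-squares line through
$(\ln r, \ln A(r))$, and local dimensions at $r = 2..5$ use the forward
two-point slope, labelled by the physical scale $r \times$ pixel size
(0.30, 0.44, 0.59, 0.74 mm at 0.148 mm pixels). A horizontal rod is
blind to variation along its own axis only in the vertical direction's
complement, so it measures the roughness of *vertical* structures
(FD~Ver~); a vertical rod gives FD~Hor~. Transposing the ROI swaps the
two exactly.

**Conventions that needed deciding.**

- *Valid interior.* All $r$ share the interior where the longest
  ($r = 7$) element fits; no padding. Boundary handling then cancels
  between scales instead of contaminating the small-$r$ versus
  large-$r$ comparison.
- *Even-length anchoring.* Elements are anchored with origin offset
  $\lfloor (r-1)/2 \rfloor$ from the left/top cell; the choice cancels
  in $V$ over the fixed interior.
- *Global fit points.* All six $A(r)$ points enter the global
  regression; the local dimension uses the minimal (two-point) reading
  of "local" consistent with four reported scales.
- *Degenerate textures.* Any $A(r) \le 0$ (a constant ROI) raises a
  classed error naming the ROI rather than returning `-Inf` slopes.

Grayscale-affine invariance ($aI + b$, $a > 0$) holds to numerical
precision because flat morphology commutes with monotone affine maps
and $\log$-slopes ignore the scale factor; this is tested at 1e-9.

## 3. The synthetic cohort generator

The generator is first-class, tested code that defines the package's
reference study conditions; real radiographs are not distributed.

**Texture.** Trabecular bone is emulated by spectral synthesis of a
fractional Brownian surface: complex Gaussian Fourier coefficients
shaped by amplitude $\propto (f_x^2 + (a f_y)^2)^{-(H+1)/2}$ (power
spectrum $|f|^{-(2H+2)}$), zero DC, inverse FFT, then an exact affine
rescale to the requested mean and SD. The closed-form ground truth
FD $= 3 - H$ is what makes the blanket-method oracle possible: measured
global FD over 10 seeds at 256² recovers $3 - H$ within 0.15 for
$H \in \{0.3, 0.5, 0.7\}$, with a small positive bias (≈ +0.1) from
discretization at small $r$ that is characteristic of blanket
estimators. The default cohort is isotropic ($a = 1$) precisely so this
oracle applies; anisotropy is a supported knob but then the directional
Hurst truth is no longer a single closed-form number.

**Group effects.** Densities are drawn per ROI band: medial
subchondral bone 26.9/29.2/29.6 mm Al (SD 3.1/4.7/4.5) for
control/OA/BML, the medial grid band 20.1/22.3/24.0 (SD 2.1/2.9/4.0) —
the published effect sizes for calibrated knee density — and flat
lateral bands where disease effects are small. Roughness follows group
Hurst exponents 0.35/0.32/0.29 in the medial bands, chosen so vertical
FD rises with disease by a few hundredths, matching the published
texture effect sizes in direction and magnitude. Covariates are
independent group-wise normals (age 56.4/58.3/60.8 ± 6.3/5.5/4.4 y;
BMI 25.0/28.1/30.9 ± 2.5/3.8/5.8 kg/m²; sex balanced), because only
marginal summaries are published. Group sizes default to 20/15/10.

**Clinical post-processing simulator.** Vendor algorithms are
proprietary; their public description is nonlinear contrast adjustment
plus edge enhancement. The simulator composes exactly that: a logistic
contrast remap (center 12000, width 4000 on the 16-bit scale, spanning
the wedge and bone grayscales) followed by unsharp masking (gain 1,
Gaussian σ = 2 px), clipped to the valid range. With these defaults
the FD shift at the 0.74 mm scale is about twice the shift at 0.30 mm,
reproducing the qualitative observation that coarse-scale texture is
the more processing-sensitive readout.

**What the generator does *not* emulate.** Real anatomy (bone
contours, cortices, overlying soft tissue gradients), X-ray physics
(beam hardening, scatter, heel effect), spatially adaptive or
image-dependent vendor processing, and radiologist grading noise. Two
consequences deserve emphasis. First, because the simulated PP is a
fixed global transform, raw GV remains highly rank-correlated between
PP modes here; the package's PP-robustness test therefore asserts the
*ordering* (calibrated density correlates better than raw GV), not the
dramatic real-world decorrelation of uncalibrated grayscale. Second,
classification AUCs on synthetic cohorts (typically > 0.9) exceed
published values (≈ 0.77–0.85) because every injected effect is clean
and every ROI informative; the acceptance check is a lower bound
(AUC > 0.70), not a claim of matching clinical performance.

## 4. Group statistics

Routing follows normality: Shapiro–Wilk per variable for correlations
(Pearson if both pass, Spearman otherwise) and per group for the
three-group comparison (ANOVA with pooled-variance pairwise t tests if
all three pass, otherwise Kruskal–Wallis with Dunn's tie-corrected z).
The routing threshold is 0.05, the conventional default where no
other value is mandated. Bonferroni
multiplies each pairwise p by the family size 3 (the three pairwise
contrasts per variable); no across-variable correction is applied, by
design. Correlation strength labels use the closed two-decimal bins
(0.00–0.19 very weak … 0.80–1.00 very strong), applied after rounding
the estimate to two decimals so 0.59 is "moderate" and 0.60 "strong".
Constant vectors, on which Shapiro–Wilk is undefined, are treated as
non-normal; an all-tied comparison reports omnibus p = 1. Pooled
(rather than Welch) t tests were chosen as the classical ANOVA post
hoc; covariates are deliberately not entered into group comparisons —
they participate only in the classification models.

## 5. Classification

Elastic-net logistic regression in the glmnet parameterization
(λ·[α‖β‖₁ + (1−α)/2‖β‖₂²] added to the mean negative log-likelihood,
intercept unpenalized, features standardized internally, coefficients
reported on the original scale). The hyperparameter grid is
α = 0.1..1 step 0.05 and λ = 0.001..0.15 step 0.009, which contains the
published optima (1, 0.118) and (0.8, 0.037) by construction.

Selection maximizes the **pooled** leave-one-out AUC: with
single-subject folds a per-fold AUC does not exist, so each subject's
out-of-fold probability is pooled and scored once. Ties break toward
the sparser model (larger λ, then larger α). The final model is refit
on all data at the selected pair; both the pooled cross-validated AUC
(primary) and the refit model are exposed. Missing features (excluded
ROI densities) are median-imputed strictly within training folds.
Covariates (age, sex as a 0/1 indicator, BMI) enter a *separate*
augmented model and are penalized like any other column — no published
exception exists, and an unpenalized-covariate flag would change the
printed α/λ semantics.

One structural caveat, measured rather than assumed: pooled LOOCV
probabilities are mildly *pessimistic* under the null, because leaving
out a subject lowers its own class's training prevalence. On pure-noise
labels the selected AUC scatters widely around a mean near 0.45; the
no-optimism test therefore averages over replicate noise datasets.

DeLong AUC variance and 95% CIs come from pROC with the orientation
fixed (higher score ⇒ positive class), so AUC is exactly the
Mann–Whitney probability with ties counted ½ and sign-reversal maps
AUC to 1 − AUC.

## 6. Problem sizes used by the tests

The unit suite runs on a geometrically scaled cohort (5 mm grid ROIs,
420 × 560 px canvas) so a ten-subject cohort generates in seconds; the
physics — wedge response, saturation, group effects — is identical to
the reference configuration. The acceptance layer uses the reference
conditions themselves: 256² textures for FD recovery (10 seeds per
Hurst value), 2000 null replicates for the omnibus type-I error at
group sizes 20/15/10, and five (tests) or three (acceptance script)
full 45-subject pipeline runs for the group-difference and AUC checks.
On the reference cohorts the medial-subchondral density contrast
(26.9/29.2/29.6, SD up to 4.7) has only ≈ 45% omnibus power at
n = 20/15/10 — a property of those effect sizes, not of the pipeline —
so the significance check targets the medial grid band (anchored to
the strongest published density row, ≈ 90% power) while the medial
subchondral ROI is checked for the induced ordering
control < OA ≤ BML of its seed-averaged group means.

## 7. Known limitations

- The 16-ROI grid geometry is a documented convention (2 × 8 square
  10 mm ROIs with 1 mm gaps, numbered medial→lateral, top row first),
  not a reconstruction of any particular clinical layout; it is fully
  configurable via `roi_layout()`.
- Landmark placement is deterministic from supplied coordinates; no
  automatic bone segmentation is attempted.
- DICOM input is not supported (16-bit TIFF and PNG are); convert
  upstream if needed.
- The generator's minimal-PP transfer curve is assumed linear in the
  wedge-response cubic; detector log-dose responses would change the
  cubic's shape but not the calibration logic, which never leaves the
  fitted range.
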