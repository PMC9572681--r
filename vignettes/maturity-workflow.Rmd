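---
title: "Hyperspectral maturity grading: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral maturity grading: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleaspec)
```

`oleaspec` grades the ripeness of oilseed fruit (five ordinal stages,
S1–S5) from visible/near-infrared hyperspectral images. This vignette is
the package's own account of the science: the models it fits, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open.

## The measurement model

A pushbroom hyperspectral camera records raw counts `I_r(x, y, λ)`. With a
white reference `I_w` (a diffuse ~100% reflectance target) and a dark
frame `I_d` (lens capped), relative reflectance is

$$I_c = \frac{I_r - I_d}{I_w - I_d},$$

stored as a fraction (1.0 = 100%). The transform is invariant to any
common affine rescaling of the three inputs, which is exactly the claim
that it removes uneven illumination and dark current; a unit test asserts
this invariance directly. Elements where `I_w ≤ I_d` (dead pixels) become
`NA` with a warning rather than infinities, so downstream masking always
sees finite numbers. References may be full frames (per-pixel, the
default) or collapsed to one scalar per band; per-pixel is the default
because flat-field structure is the main reason to record a white frame at
all.

The fruit is isolated by band math: the image plane nearest 862 nm (bright
fruit, NIR plateau) minus the plane nearest 416 nm (dark fruit, pigment
absorption) yields a high-contrast greyscale image; pixels strictly above
a reflectance threshold of 0.1 form the mask. Two small choices are worth
recording: "the image at λ nm" is resolved by nearest-band lookup with the
band actually used reported in an attribute (a stated wavelength need not
exist on the grid), and the threshold comparison is strict, so the
boundary value 0.1 itself is background. No morphological cleanup or
smoothing is applied — none is needed for single-fruit scenes on a dark
background, and every extra operation would be one more undocumented
degree of freedom. The sample's spectrum is the mean over mask pixels
only; zeroed background never enters the average, and an empty mask is an
error rather than a silent `NaN`.

## Preprocessing

Four standard pre-treatments are available, applied row-wise (per
spectrum) after trimming to 400–1000 nm:

* **SNV** — centre to mean 0, scale to unit sd (n−1). Removes per-spectrum
  additive offset and multiplicative gain.
* **Max–min normalization** — rescale each spectrum onto exactly [0, 1].
  Same invariance class as SNV.
* **Savitzky–Golay derivatives** (orders 1 and 2) — local least-squares
  polynomial fit, window 7, polynomial order 2, differentiated at the
  window centre.

Two open details were settled as follows. *Edges:* the polynomial fitted
to the first/last full window is evaluated at the edge points, so no bands
are lost and every preprocessed table keeps all 119 columns; this matches
the windowed-polyfit oracle the tests compare against. *Derivative
scale:* derivatives are per band-index step, not per nm — classification
is invariant to a global rescaling of the derivative, and instrument grids
are not always uniform in nm, so rescaling would add a convention without
adding information. Since all per-spectrum transforms use no training
statistics, preprocessing cannot leak information from held-out samples by
construction.

## Classifiers

**PLS-DA.** One PLS1 (NIPALS) regression per stage against its {0, 1}
indicator; a sample is assigned to the class with the largest regression
response, ties to the lowest stage index (a deterministic, documented
rule — the coding and assignment rule are conventions the method itself
does not fix). Spectra are mean-centred but not autoscaled; NIR bands
share a common scale, and autoscaling would inflate noisy bands. The
latent dimension (1..20 by default, mirroring the sizes typical for this
problem) minimizes the misclassification count under ten-fold
Venetian-blinds cross-validation — fold *f* holds calibration rows
*f*, *f*+10, *f*+20, … in table order, so the fold assignment is
deterministic given the table; ties go to the smaller dimension. PRESS on
the indicator responses is available as an alternative criterion.

**PCA-DA.** PCA on the calibration spectra, then equal-prior linear
discriminant analysis (pooled within-class covariance) on the first *p*
un-rotated score dimensions, with *p* chosen by the same cross-validation
(PCA and LDA are refitted inside every fold). A singular within-class
covariance triggers a stepwise reduction of *p* with a warning. The LDA
step delegates to `MASS::lda`; an explicit pooled-covariance discriminant
serves as the independent oracle in the tests.

## Wavelength selection

Three selectors, all fitted on the calibration split only:

* **PC loading peaks** — local extrema (maxima and minima) of the first
  three loading lines, kept when their topographic prominence reaches 10%
  of that line's range (the prominence threshold is a free parameter; 10%
  suppresses ripple without hiding genuine features). Wavelengths picked
  by several components are merged only when they are the identical band.
* **Synchronous 2D-COS** — the five stage-mean spectra, ordered S1→S5,
  form the perturbation series; dynamic spectra are deviations from the
  perturbation-mean reference (the usual convention when no reference
  state is singled out), and Φ = ỸᵀỸ/(m−1). Autopeaks are prominent local
  maxima of the diagonal. Φ is symmetric positive semidefinite with
  per-band dynamic variance on its diagonal — both are asserted as
  invariants.
* **UVE + SPA** — UVE augments the spectra with as many artificial
  uniform-noise variables as real bands, scaled by 1e−10 so they cannot
  influence the fit; resampled PLS1 submodels of the class indicators give
  each variable a stability `s = mean(b)/sd(b)`, and real variables must
  beat the maximum |s| of the artificial block (a 99th-percentile cutoff
  is available when the max is too conservative). With five classes the
  submodels are fitted per class; a variable's stability is its largest
  magnitude across classes, so a band informative for any one stage
  survives. SPA then walks the retained candidates: from each start, it
  repeatedly adds the candidate with the largest residual norm after
  projection onto the orthogonal complement of the span already chosen
  (ties to the lowest band index, which makes selection order invariant to
  candidate permutation); each chain prefix is scored by Venetian-blinds
  cross-validated RMSE of an indicator PLS-DA restricted to those bands,
  and the global RMSE minimum wins, ties to fewer bands.

Two UVE details deviate from the most common textbook presentation, for
measured reasons. The resampling is Monte-Carlo (100 random 80% subsets)
rather than leave-one-out: on calibration sets of a hundred-plus samples,
removing a single row perturbs the fit so little that real and artificial
variables have indistinguishable stability distributions (we measured
overlapping medians and a cutoff that eliminated essentially everything);
leave-one-out remains available for small-n work. The submodel dimension
defaults to the cross-validation-chosen PLS-DA dimension of the table at
hand rather than a fixed constant — at a fixed large dimension the
submodels overfit and stability collapses for all variables equally.

## The synthetic scene generator

The generator is first-class, tested code; it defines the study conditions
the acceptance checks run under.

Each scene is an ellipsoidal fruit (default 48×48 px frame, semi-axes
13×16 px) on a dark background (reflectance 0.02). The fruit's true
spectrum is a smooth envelope — low in the visible, rising sigmoidally
around 700 nm to a NIR plateau — minus Gaussian absorption dips at 416,
672, 862 and 979 nm (sd 12/16/20/22 nm). Depth-versus-stage profiles:

| feature | S1 | S2 | S3 | S4 | S5 | reading |
|---|---|---|---|---|---|---|
| 416 nm | 0.145 | 0.118 | 0.100 | 0.108 | 0.085 | pigment decay |
| 672 nm | 0.200 | 0.170 | 0.140 | 0.110 | 0.080 | chlorophyll, strictly ↓ |
| 862 nm | 0.010 | 0.040 | 0.052 | 0.038 | 0.012 | moisture, mid-season peak |
| 979 nm | 0.040 | 0.068 | 0.056 | 0.080 | 0.088 | water/carbohydrate |

The profiles are deliberately *affinely independent*: the centred
class-mean matrix has singular values ≈ 0.109/0.038/0.017/0.012, so the
five stages span a well-conditioned simplex in feature space. This is not
cosmetic. One-vs-rest linear indicator regression — which is what PLS-DA
is — structurally masks middle ordinal classes when the class means lie
near a line or thin curve: the middle indicators need bump-shaped
functions a linear model cannot represent, and we verified that on a
near-collinear profile set even noise-free data caps far below usable
accuracy while LDA is untroubled. Real ripening changes several
constituents at different, crossing rates (oil accumulates monotonically
while seed moisture peaks and falls), which is precisely what gives real
spectra their multi-dimensional class geometry; the defaults encode that.

Stochastic corruptions, per scene: per-sample jitter of every feature
depth (sd 0.005, truncated at 0 — within-stage biological variability);
multiplicative scatter `1 + 0.10·(0.6 u_scene + 0.4 u_pix)` and additive
offset `0.02·(0.6 v_scene + 0.4 v_pix)` with all `u, v ~ U(−1, 1)` (the
scene-level share models illumination drift between acquisitions, the
pixel-level share surface texture — the distortions SNV and derivatives
exist to remove); and per-pixel Gaussian noise (sd 0.02 reflectance).
Scenes are embedded into raw counts as `raw = dark + (white − dark)·R`
with a smooth per-band white illumination shape, so calibration exactly
inverts the embedding: with all corruptions at zero the calibrated scene
equals the analytic truth bitwise, which is the package's master
round-trip oracle. Geometry (ellipse centre/axes) is jittered per sample;
a dataset shares one white/dark pair, as a real acquisition session would.

Under these defaults a 200-fruit study (40 per stage, 3:1 stratified
split) gives full-spectrum prediction CCRs around 96–100% across
preprocessings and models, a label-permutation cross-validation CCR
statistically at the 20% chance level, and wavelength selectors that place
bands within a few nm of the planted 672 nm feature. Those problem sizes —
200 scenes of 48×48×119, chosen so a full acceptance run completes in
about a minute — are also the sizes the test suite uses.

What the generator does **not** emulate: fruit surface texture and
curvature shading, specular highlights, multi-fruit scenes and shadows,
spectral smile or keystone, wavelength-dependent noise, cracked/overripe
fruit, and any radiometric model of a specific camera. Passing tests
therefore demonstrate that the *algorithms* are correct and that the
pipeline recovers known structure under realistic scatter and noise — not
that any particular instrument will reach these accuracies on real fruit.

## Numerical choices and degenerate inputs

* Wavelength grid: 119 evenly spaced points on [400, 1000] nm. A stated
  instrument resolution of 2.8 nm is inconsistent with 119 bands over that
  range; even spacing of the stated band count was chosen, and the grid is
  fully configurable.
* PCA loadings are sign-canonicalized (largest-magnitude element positive)
  so results are deterministic across BLAS implementations.
* SPA declares a candidate span exhausted when the best residual norm
  falls below 1e−10 of the starting scale, truncating the chain with a
  warning (duplicate columns can never be selected twice).
* PLS/NIPALS stops early when the weight or score norm underflows 1e−12;
  coefficient columns for unreachable dimensions repeat the last reachable
  one.
* Constant spectra are an error in SNV/max–min (the offending sample is
  named); empty masks, empty band windows, single-class tables,
  out-of-range labels and mismatched shapes all raise immediate errors.
* Confusion reports keep raw unrounded ratios; the printer rounds
  percentages to one decimal and ratios to two, the field's reporting
  convention. A class never predicted has `NaN` precision plus an
  explanatory note instead of a silent 0/0.
* All randomness (scenes, jitter, splits, UVE noise block, Monte-Carlo
  subsets, permutations) flows from explicit integer seeds; fits and
  predictions contain no randomness at all.

## Known limitations

The classifiers are linear; strongly non-linear class boundaries would
need kernel or tree-based methods outside this package's scope. The
Venetian-blinds fold rule is defined on table row order, so shuffling rows
changes the cross-validation estimate (documented, deterministic
behaviour). UVE's artificial-variable magnitude (×1e−10) follows common
practice but is a convention. 2D-COS here uses the five class-mean spectra
as the perturbation series; using all individual spectra would weight
stages by sample count instead. Asynchronous 2D-COS is not implemented —
it is not used for band selection in this workflow.
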