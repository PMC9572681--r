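# oleaspec

Chemometrics for grading the ripeness of oilseed fruit from
visible/near-infrared (400–1000 nm) hyperspectral images.

Harvest timing drives both the yield and the quality of tea-oil extracted
from *Camellia*-type fruit, but ripeness is hard to judge from peel colour
alone. Hyperspectral imaging records a full reflectance spectrum at every
pixel, so a fruit's maturity signature — chlorophyll breakdown around
672 nm, water/carbohydrate overtones near 862 and 979 nm, pigment
absorption near 416 nm — can be read out non-destructively. `oleaspec`
implements the complete analysis chain needed to turn raw hypercubes into a
five-stage maturity classifier, plus a synthetic scene generator with known
ground truth so every stage is testable without instrument data.

## What it does

Given a raw hypercube `I_r` with white and dark reference frames
`I_w`, `I_d`:

1. **Calibration** — per-element reflectance
   `I_c = (I_r − I_d) / (I_w − I_d)` (`calibrate()`), ENVI header/binary
   I/O (`read_cube()` / `write_cube()`).
2. **Segmentation** — band math (image at 862 nm minus image at 416 nm),
   binary mask at a reflectance threshold of 0.1, and mean-spectrum
   extraction over the fruit pixels (`band_math()`, `threshold_mask()`,
   `apply_mask()`, `mean_spectrum()`).
3. **Preprocessing** — band trimming to 400–1000 nm, standard normal
   variate, max–min normalization, Savitzky–Golay 1st/2nd derivatives
   (window 7, 2nd-order polynomial).
4. **Classification** — PLS-DA (one PLS1/NIPALS indicator regression per
   stage, argmax assignment) and PCA-DA (equal-prior LDA on un-rotated PC
   scores), each with its dimension chosen by ten-fold Venetian-blinds
   cross-validation (`plsda_fit()`, `pcada_fit()`, `cv_curve()`).
5. **Wavelength selection** — PCA loading-line peaks (`loading_peaks()`),
   synchronous two-dimensional correlation spectroscopy with maturity as
   the perturbation (`synchronous_2dcos()`, `autopeaks()`), and
   uninformative variable elimination chained with the successive
   projections algorithm (`uve_select()`, `spa_select()`, `uve_spa()`).
6. **Evaluation** — K×K confusion matrices with per-class CCR,
   sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and precision
   `TP/(TP+FP)` (`confusion()`, `evaluate_splits()`).

`run_full_comparison()` and `run_selection_comparison()` orchestrate the
full study design: a 3:1 stratified calibration/prediction split, the
2 model × 5 preprocessing grid, and simplified models refit on selected
wavelengths.

## Worked example

Score a published five-stage prediction confusion matrix (shipped as a
plain-text fixture):

```r
library(oleaspec)
rep_ <- confusion_from_counts_csv(
  system.file("extdata", "prediction_confusion_published.csv",
              package = "oleaspec"))
print(rep_)
#> Confusion matrix (rows = actual, cols = predicted)
#>    S1 S2 S3 S4 S5 CCR   Sensitivity Specificity Precision
#> S1 49  1  0  0  0 98.0% 0.98        0.95        0.83
#> S2  8 37  1  1  3 74.0% 0.74        0.95        0.80
#> S3  2  2 40  4  2 80.0% 0.80        0.94        0.78
#> S4  0  4  7 33  6 66.0% 0.66        0.97        0.85
#> S5  0  2  3  1 44 88.0% 0.88        0.94        0.80
#> Overall CCR: 81.2% (203/250)
```

Rows are the true stages, columns the predicted ones; most confusion sits
between adjacent mid-season stages (S2–S4), whose spectra differ least.

End-to-end on synthetic scenes — simulate 50 fruit (10 per stage),
extract spectra, split 3:1, fit PLS-DA on 2nd-derivative spectra:

```r
tbl <- simulate_spectra(10, seed = 1)
tbl <- assign_split(trim_bands(tbl), seed = 2)
tp  <- preprocess(tbl, "d2")
fit <- plsda_fit(tp)
ev  <- evaluate_splits(fit, tp)
#> <PLS-DA> 5 classes, 2 latent variable(s) (CV over 1..20), preprocessing: d2
#> calibration 97.5% | cross-validation 97.5% | prediction 90.0%
```

The three numbers are correct-classification rates on the calibration set
(resubstitution), the Venetian-blinds cross-validation, and the held-out
prediction set.

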