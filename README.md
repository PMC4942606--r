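# snomchemo

Chemometrics for infrared cytopathology: an end-to-end, tested pipeline for
the two measurement arms used to characterise cervical cytology specimens
with vibrational spectroscopy.

* **SNOM-IR arm** — scanning near-field optical microscopy transmission
  images, one 150 × 150 pixel matrix per cell per fixed biomarker wavelength
  (lipids 5.71 µm, Amide I 6.06 µm, Amide II 6.46 µm, DNA νasPO₂⁻ 8.16 µm).
  Each image `X` is reduced to a *spectrum-like signal* by averaging over
  the slow-scan direction,

  `s_j = (1/m) Σ_{i=1..m} x_ij ,  j = 1..c`

  then normalized by mean-centring and absolute value,
  `s ← |s − mean(s)|`. The biomarker content of a cell is quantified as the
  trapezoidal area `A` of the normalized, replicate-averaged signal over the
  spatial interval covering the cell, and each abnormal class is summarised
  by its percentage area change from the normal class,
  `ΔA% = 100 (A − A_normal) / A_normal`. Per-biomarker PCA score plots with
  Hotelling T² and Q-residual 95% limits assess sample homogeneity.

* **ATR-FTIR arm** — fingerprint-region spectra classified with the
  standard biospectroscopy workflow: a Kennard–Stone maximum–minimum
  distance split into training (70%), validation (15%) and prediction (15%)
  sets; PCA-LDA with the component count chosen on the validation set; and
  SPA-LDA, successive-projections variable selection scored by the G cost
  (mean ratio of a validation sample's squared Mahalanobis distance to its
  own class mean over the distance to the nearest rival class mean).

Because raw SNOM images and patient spectra of this kind are rarely
deposited, the package ships a first-class synthetic-data module that
emulates both measurements with known class structure — tapered-ellipse
cell footprints with class/biomarker-dependent absorption for the image
arm, Gaussian band spectra at the ten discriminant wavenumbers (1022, 1157,
1184, 1234, 1331, 1512, 1566, 1662, 2345, 2939 cm⁻¹) for the spectral arm —
so every stage can be validated against ground truth.

## Worked example

```r
library(snomchemo)

## SNOM arm: noise-free synthetic dataset, default class effect table
cfg <- snom_sim_config(noise_sd = 0, line_offset_sd = 0)
ds  <- generate_snom_dataset(cfg, seed = 1)
rep <- run_snom_pipeline(ds)
head(subset(rep$area_table, class_label != "normal"), 4)
#>             class_label biomarker interval_lo_um interval_hi_um   area delta_area_pct
#> 5 low_grade_dyskaryosis    lipids              0          397.3  63.93            -31
#> 6 low_grade_dyskaryosis   amide_I              0          397.3  25.02            -73
#> 7 low_grade_dyskaryosis  amide_II              0          397.3 225.16            143
#> 8 low_grade_dyskaryosis       dna              0          397.3 195.51            111
```

The `delta_area_pct` column recovers the class effects the generator
planted: with noise off, the signal extraction is linear in the absorption
amplitude, so a class simulated at 0.69× the normal lipid amplitude comes
back as exactly −31%. Low-grade dyskaryosis shows the characteristic
pattern of depressed Amide I and lipids with elevated Amide II and DNA.

```r
## ATR arm: Kennard-Stone split, PCA-LDA and SPA-LDA
atr <- generate_atr_dataset(atr_sim_config(), seed = 2)
res <- run_atr_pipeline(atr)
res$pca_lda$chosen_A
#> [1] 2
res$spa
#> <spa_result> 2 variables selected (G = 0.001582):
#>   1564, 1668
c(res$pca_lda_accuracy, res$spa_lda_accuracy)
#> [1] 1 1
```

Both classifiers reach 100% accuracy on the held-out prediction set, and
SPA selects axis points sitting on the planted Amide II (1566 cm⁻¹) and
Amide I (1662 cm⁻¹) bands — the wavenumbers that best separate the five
simulated classes.

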