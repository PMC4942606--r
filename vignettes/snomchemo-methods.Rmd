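---
title: "Methods: image reduction, biomarker areas and spectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image reduction, biomarker areas and spectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snomchemo)
```

# The measurement model

`snomchemo` analyses two kinds of infrared measurements of cervical
cytology specimens.

**Transmission images.** A SNOM tip scans a cell at one fixed wavelength
tuned to a biomarker vibration (lipids ~1750 cm⁻¹ / 5.71 µm, Amide I
~1650 cm⁻¹ / 6.06 µm, Amide II ~1550 cm⁻¹ / 6.46 µm, DNA asymmetric
phosphate ~1225 cm⁻¹ / 8.16 µm), producing a pixel matrix `X` (rows =
slow-scan lines, columns = fast-scan positions). The quantitative chain is:

1. *Reduction* (`image_to_signal`): the matrix is collapsed to a
   spectrum-like row vector by the column-wise mean over the slow-scan
   direction, `s_j = (1/m) Σ_i x_ij`. The phrase "mean in the column-mode
   direction" is dimensionally ambiguous on a square matrix; we read it as
   *the mean runs over rows, producing one value per column*, which is the
   reading consistent with a 1 × 150 row vector arising from a 150 × 150
   matrix and with a fast-scan spatial axis.
2. *Normalization* (`normalize_signal`): mean-centring followed by absolute
   value, in that order. Centring removes the (uninformative) transmission
   background level; the absolute value folds both polarities of deviation
   into a non-negative profile whose area is a meaningful amount of
   "biomarker contrast". Normalizing an already-normalized signal is an
   error by contract, since `||x − mean|x − mean||` is not the same quantity.
3. *Replicate averaging* (`average_replicates`): each biomarker is imaged in
   triplicate; replicates are combined pointwise. The default order is
   normalize-each-replicate-then-average: normalization is nonlinear, so the
   two orders differ on noisy data, and normalizing first prevents one
   replicate's background offset from bleeding into the others. The
   alternative order is available as a switch (`order =
   "average_then_normalize"`) for sensitivity checks.
4. *Area and ΔA%* (`signal_area`, `delta_area_percent`): the normalized
   signal is integrated by trapezoidal quadrature over a spatial interval
   covering the cell. Trapezoid is exact for piecewise-linear signals and is
   the natural rule on a uniform pixel-pitch axis. Interval endpoints are
   snapped to the nearest axis points and the snap is reported. When no
   hand-picked interval is supplied, the fallback (`auto_interval`) takes
   the smallest interval containing all points above half the signal
   maximum, padded by 10% of the axis span — an automated stand-in for
   selecting the interval "by eye" from the cell position. Each class's
   biomarker area is then expressed relative to the normal class,
   `ΔA% = 100 (A − A_ref)/A_ref`; this is the unique convention under which
   a class with 6.85× the normal DNA amplitude reports +585%, about half of
   +1272% at 13.72×.
5. *PCA diagnostics*: per biomarker, the class-average normalized signals
   are decomposed by mean-centred SVD; Hotelling T² and Q residuals with
   95% limits flag outlying samples. With only five class-average signals
   the limits are poorly determined; the pipeline logs a small-sample
   caveat whenever `n ≤ A + 1`.

A separate *presentation-only* channel (`enhance_image`) reproduces the
visual clean-up applied to published images — row-median line correction
followed by a radial 2-D Fourier low-pass. It is deliberately excluded from
the analysis path: quantitative results are always computed from raw
pixels, and the function flags its output accordingly.

**ATR-FTIR spectra.** Spectra over a 900–3100 cm⁻¹ axis at 8 cm⁻¹ spacing
are classified after a deterministic Kennard–Stone split (70% training /
15% validation / 15% prediction). Two classifiers are built:

* **PCA-LDA** (`pca_lda_train`): PCA scores of the training set feed a
  Mahalanobis linear discriminant; the number of components is chosen on
  the validation set.
* **SPA-LDA** (`spa_lda_select`): the successive projections algorithm
  grows, from every starting variable, a chain of maximally
  non-collinear variables (largest residual norm after orthogonal
  projection onto the span of the chain); every chain prefix is scored on
  the validation set and the global minimizer is selected.

Both are scored with the **G cost**: for validation sample `n` with true
class `I(n)`, `g_n = r²(x_n, m_I(n)) / min_{J≠I(n)} r²(x_n, m_J)` with `r²`
the squared Mahalanobis distance under the training pooled covariance, and
`G` the mean of `g_n`. G is zero when every sample sits at its own class
mean, and below one on average when samples are closer to their own class
than to any rival. The literature on SPA-LDA names this cost but rarely
prints it; the ratio-of-squared-distances form used here is the standard
one, and we document it as our operational definition. Model selection by
validation *accuracy* instead of G is available (`criterion =
"accuracy"`); G is the default because it is continuous in the data and
breaks ties that a coarse error count cannot.

# The synthetic-data generator

No public archive provides raw SNOM transmission matrices or the matching
patient spectra, so validation is built around a generator whose defaults
*are* the study conditions.

**Images** (`snom_sim_config`, `generate_snom_image`): 150 × 150 pixels over
400 µm × 400 µm, four biomarker wavelengths, three replicates per
biomarker. The cell is a filled ellipse with a cosine-tapered rim — real
cells are irregular, but signal extraction only needs a compact footprint
with a smooth edge, and a parametric shape makes every downstream quantity
predictable. Absorption is *added* to a uniform background
(`polarity = "absorption"`): the raw polarity of a transmission signal is
instrument-dependent and is not fixed by a colour scale that reports
"increasing absorption", so polarity is a config switch with
absorption-positive default; the mean-centring-plus-absolute-value
normalization makes the analysis invariant to this choice. Noise is i.i.d.
Gaussian per pixel (σ = 0.02 against a unit-amplitude cell, a mid-range
SNR for scanning-probe transmission data) plus a per-line offset
(σ = 0.01) emulating slow-scan drift; the lipid channel gets 3× noise,
reflecting the weaker source signal at 5.71 µm.

The per-class absorption multipliers (`default_effect_table`) are set to
`1 + ΔA%/100` with the published percentage area changes for the four
biomarkers: because the extraction chain is linear in the absorption
amplitude, a noise-free run then returns exactly those percentages, making
the round trip a sharp end-to-end test. Only the *sign pattern* of the
table is treated as ground truth to recover; the magnitudes are a
convenient, faithful parameterisation.

**Spectra** (`atr_sim_config`, `generate_atr_dataset`): Gaussian bands
(σ = 16 cm⁻¹, a typical condensed-phase band width at this sampling) at
the ten discriminant wavenumbers, ten spectra per class, baseline 0.05,
noise σ = 0.01. The default per-class amplitude matrix gives every pair of
classes clearly distinct amplitudes at three or more fingerprint bands —
elevated phosphate/nucleic-acid and Amide II bands in dyskaryotic and
pre-invasive classes, depressed glycogen and Amide I — amplitudes are
configuration, not hard-coded truth. Band shape is a modelling choice: the
source data do not constrain band profiles at all, and Gaussians are the
simplest profile with local support on this axis.

What the generator does *not* emulate — irregular and ruptured cells,
tip–sample artifacts, topographic cross-talk, baseline drift and
scattering distortions in ATR spectra, patient-to-patient variability —
bounds what passing tests demonstrate: they validate the computational
chain (the estimators, their contracts and their selection behaviour), not
the clinical performance of the method on real specimens.

# Numerical choices and degenerate inputs

* **PCA sign convention**: each loading column is flipped so its
  largest-magnitude element is positive — SVD signs are otherwise
  arbitrary and platform-dependent, and a fixed convention makes reports
  bit-reproducible.
* **T²/Q limits**: T² uses the F-distribution limit
  `A(n−1)/(n−A) · F₀.₉₅(A, n−A)`; Q uses the Jackson–Mudholkar
  approximation from the residual eigenvalues (residual eigenvalues below
  `1e−12 ×` total variance are treated as numerically zero; at full rank
  the Q limit is reported as 0 and no Q outliers are flagged).
* **Kennard–Stone**: run once, globally, on raw intensities — the classic
  algorithm, with no per-class stratification or scaling. Ties (equal
  distances, including the all-duplicates degenerate case, which warns)
  break to the lowest sample index. Set sizes: `round(0.70 n)` for
  training, then `round(0.15 n)` for validation, prediction takes the
  remainder.
* **LDA**: pooled within-class covariance with divisor `n − K`; when the
  smallest eigenvalue falls below `1e−10 × trace/d` a ridge of
  `1e−8 × trace/d` is added (necessary whenever the feature count
  approaches the training count, e.g. full spectra at n = 50).
  Classification ties go to the lowest class index and are logged.
* **Model-selection ties**: smallest model wins — fewest components, then
  fewest variables, then the lexicographically smallest index set.
  Parsimony plus determinism.
* **SPA chains** stop early when every remaining projected column norm
  falls below `1e−10 ×` the largest initial norm; zero-variance starting
  columns are skipped with a message.

# Problem sizes

The shipped tests and the acceptance script run at the study's own scales:
60 images of 150 × 150 pixels (5 classes × 4 biomarkers × 3 replicates)
for the image arm; 50 spectra × 276 variables for the spectral arm;
10 000 Monte-Carlo draws for the T² coverage check; 30-variable planted
datasets (choose(30, 3) = 4060 exhaustive subsets) for SPA recovery. Unit
tests use smaller fuzzed matrices (≤ 20 × 20) where the property under
test is size-independent.

# Known limitations

* One cell per class: the image arm quantifies *this specimen set*, not
  class-level biology; ΔA% carries no replicate-level uncertainty.
* The interval fallback assumes one dominant contiguous cell footprint per
  signal; multiple cells in a scan would need hand-picked intervals.
* The G cost requires every validation class to be present in training; a
  Kennard–Stone split of a very small or very unbalanced dataset may not
  satisfy this, and the pipeline fails loudly rather than silently
  reweighting.
* No spectral pre-processing (derivatives, SNV, baseline correction) is
  applied or provided — the workflow operates on raw spectra by design.
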