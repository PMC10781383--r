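---
title: "Estimating leaf pigment content from six-band proximal imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf pigment content from six-band proximal imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Total chlorophyll (Chl a+b) and carotenoid (Car) contents, in µg/cm², are
the standard leaf-scale indicators of photosynthetic capacity and stress in
broadleaf trees such as poplar. Wet-lab determination (ethanol extraction,
UV–VIS absorbance at 665/649/470 nm) is accurate but destructive and slow.
A six-channel proximal multispectral camera (bands centred at 450, 555,
660, 720, 750 and 840 nm) images whole leaves in seconds; the question is
how far a careful chemometric pipeline can push such broadband data toward
lab accuracy, and how pigment content can then be mapped pixel by pixel.

`leafpigmentr` implements that pipeline end to end:

1. **Calibration** — counts to reflectance by ratio to a reference panel of
   known reflectance (flat-field emulation).
2. **Segmentation** — leaf mask from 840-nm reflectance > 0.25 (strict
   inequality), 8-connected labelling, small components (< 50 px) removed,
   labels ordered by area.
3. **MSC** — multiplicative scatter correction of each spectrum against the
   "ideal" (mean) spectrum of all leaf pixels in the image.
4. **Features** — the 6 bands plus 26 published vegetation indices form a
   32-variable "pseudo-hyper-spectrum"; columns are z-scored.
5. **Selection** — CORR (correlation-ordered forward filtering), SFS
   (greedy forward wrapper) and RFE (backward elimination by learner
   importance), each scored by repeated 5-fold cross-validated RMSE of a
   PLS, linear or RBF-SVM induction learner.
6. **Models** — PLSR and ε-SVR with grid-searched hyperparameters,
   validated by leave-one-out cross-validation (R², RMSE).
7. **Mapping** — the fitted model applied per leaf pixel, with per-layer
   frequency histograms comparing the pixel mean against the lab mean.

## Laboratory reference values

Extract concentrations follow the 95%-ethanol spectrophotometric system:
Chl a = 13.95·A665 − 6.88·A649, Chl b = 24.96·A649 − 7.32·A665 (mg/L), so
total chlorophyll is exactly 6.63·A665 + 18.08·A649, and carotenoids are
(1000·A470 − 2.05·Chl a − 114.8·Chl b)/245. Area contents use the
convention µg/cm² = C[mg/L] · n · V[mL] / area[cm²] (reading mg/L as
µg/mL); no worked numeric example exists to pin the unit factor, so the
package declares this convention and uses it consistently everywhere —
only internal self-consistency matters for the synthetic workflow.
Negative computed concentrations (possible for pathological absorbance
combinations) are returned unclamped with a warning so the algebraic
identities stay exact.

## The synthetic scene generator

No public image set accompanies this kind of campaign, so the generator is
a first-class module: every downstream stage is exercised on scenes whose
ground truth is known exactly.

What it emulates:

* **64 leaves in three canopy layers** on a black board with a reference
  panel in frame. Chl a+b is drawn from a truncated normal (mean 26.96,
  SD 13.02, range 2.35–54.25 µg/cm²) and Car (mean 6.10, SD 2.05, range
  2.12–9.54) is coupled to it through a Gaussian copula (r = 0.8),
  reflecting the strong Chl–Car association in field leaves. Layer shifts
  of ±6 (Chl) and ±0.8 (Car) µg/cm² make upper-canopy means lower than
  lower-canopy means. Truncation necessarily shrinks the realized
  coefficient of variation to ≈ 43–44% for Chl (the untruncated
  parameters imply 48%); with the mean, SD and bounds all pinned, the CV
  is a consequence rather than a free dial.
* **A pigment–reflectance law** R_b = R∞_b · exp(−(kChl_b·chl +
  kCar_b·car)) with plateau R∞ = (0.10, 0.55, 0.50, 0.60, 0.62, 0.62).
  Reflectance decreases with pigment content in the green, red and
  red-edge bands and is pigment-independent in the NIR. The coefficients
  are a *test fixture*, chosen once so the band–pigment correlation
  ordering is qualitatively right (red-edge and green indices most
  informative); they are not a radiative-transfer model.
* **Scatter** — each leaf receives an affine reflectance distortion
  (gain ~ LogNormal(0, 0.1), offset ~ N(0, 0.02)), the disturbance class
  MSC is designed to invert (specular reflection, leaf inclination), plus
  per-pixel Gaussian sensor noise (SD 150 counts on a 16-bit range).
* **Within-leaf structure** — a smooth pigment gradient along the leaf
  axis (±10%, renormalized so the leaf's masked map mean equals its table
  value exactly) and a darker vein skeleton (reflectance × 0.9).

What it does **not** emulate: BRDF and illumination geometry, camera
spectral response curves, band misregistration, biological residual
variation around the reflectance law, senescence patterns, or overlapping
leaves. Consequently a passing recovery test shows the pipeline's
machinery is correct — calibration inverts the forward model, MSC removes
affine scatter, selection finds the informative indices, LOOCV is
leak-free — but it does not certify field accuracy: on these clean scenes
the models reach R² ≈ 0.99, far above what real campaigns report, because
the only error sources are the ones the pipeline is explicitly built to
remove.

Counts are kept as floating-point values in [0, 65535]; quantisation to
integers happens only on 16-bit TIFF export. This keeps the
render → calibrate inversion exact in memory (panel reflectance is
recovered identically with distortions off), which the invariant tests
rely on. The exact round-trip is checked with vein contrast and pigment
gradient disabled as well: the reflectance law is nonlinear in pigment,
so a within-leaf gradient creates a Jensen gap between the mean of
pixel reflectances and the reflectance of the mean pigment.

## Numerical and design choices

* **Band aliasing** — B1..B6 = 450, 555, 660, 720, 750, 840 nm in
  wavelength order; the index registry refers to Blue, Green, Red, Edge1,
  Edge2, NIR.
* **Two formula modes** — the registry's `"as_printed"` mode follows the
  source table literally, including an MSR without the square root, an
  MSRre built on NIR − Edge1 differences, an RDVI identical to NDVI, CVI
  with Blue² in the denominator and GRNDVI using Green + Blue. The
  `"canonical"` mode substitutes the originally published forms (√ in
  MSR/MSRre, √(NIR+Red) in RDVI, Green² in CVI, Green + Red in GRNDVI).
  The default is `"as_printed"`; the mode is recorded in the feature
  table and in every fitted model. Scale invariance under a global
  reflectance rescaling is asserted per formula, and the two forms that
  genuinely lack it (printed MSRre, canonical RDVI) are flagged in the
  registry rather than "fixed".
* **Index guards** — denominators below 1e-9 in magnitude yield a masked
  (NA) value; samples with any masked index are dropped with a logged
  count, and masked map pixels are flagged as outliers.
* **Normalization** — z-score with the sample (n−1) SD; both learners are
  scale-sensitive and the 32 variables span orders of magnitude, which
  rules out leaving them raw; min–max would tie the scale to two extreme
  leaves. Parameters are stored for reuse on new pixels at mapping time.
* **CV harness** — `cv_rmse()` pools held-out predictions into a
  per-repeat RMSE and averages over repeats (default 5 × 5-fold). The
  default tuning mode is a single-level grid search sharing the
  evaluation folds: the subset's score is the grid minimum of the
  repeated-CV RMSE, i.e. the grid search determines the learner's
  parameters at each selection loop. A nested mode (inner 3-fold tuning
  per training partition) is available; it matters when the *reported*
  accuracy comes from the same folds, but final accuracies here are
  always reported from a separate leave-one-out loop, so the cheaper
  single-level search is the default for subset comparison.
* **Grids** — PLSR latent factors 1..min(15, p) (one multi-component fit
  serves the whole grid); SVR cost ∈ {0.1, 0.5, 1, 2, 5, 10} crossed
  with γ ∈ {0.005, 0.01, 0.05, 0.1, 0.5, 1}, a logarithmic coverage of
  the ranges [0.1, 10] × [0.005, 1]. The SVR ε-tube is fixed at 0.1 on
  the standardized target; the target is standardized inside each
  training fold and restored for reporting, PLSR centres only.
* **Selection details** — CORR breaks RMSE-minimum ties toward the
  smallest prefix (parsimony). SFS stops when the best candidate fails to
  improve the previous best merit; improvements below 1e-10 (relative)
  are treated as ties so a numerically perfect fit terminates the search.
  SFS re-seeds its resampling deterministically each iteration. RFE ranks
  by |coefficient| for the linear learners and, for the RBF-SVM (which
  has no native weights), by seeded permutation importance: each variable
  is permuted 10 times within the held-out folds of the recorded CV point
  and importance is the mean pooled-RMSE increase.
* **Metrics** — R² defaults to the squared Pearson correlation of
  measured vs predicted; `1 − RSS/TSS` and the literal printed form
  (whose denominator sums of first-power deviations are identically
  zero) are available behind flags for inspection. RMSE defaults to the
  root mean squared residual; the printed variant (y_i − Ȳ) is likewise
  available but not used.
* **LOOCV** — normalization *and* hyperparameter tuning are redone inside
  every fold's training part, so no statistic of a held-out sample ever
  reaches the model that predicts it.
* **Mapping** — per-pixel MSC uses the same group ideal as the leaf-mean
  correction; predictions outside the training-target range widened by
  20% per side are flagged (not dropped), emulating outlier removal in
  leaf maps; histograms use 50 equal-width bins per layer.

## Worked sizes and runtime

The default scene is 480 × 640 px with 64 leaves (~90,000 leaf pixels),
small enough that the full pipeline — render, calibrate, segment, MSC,
select by SVM-SFS, LOOCV and map — completes in a few minutes on one
core while leaving every stage statistically meaningful (n = 64 matches
the emulated campaign). Generator statistics are checked on a 5,000-leaf
draw.

## Known limitations

* The scatter model is *exactly* per-leaf affine. Difference-ratio
  indices such as MTCI and VOG1 cancel affine distortion analytically,
  so variable selection can route around scatter even without MSC; on
  these scenes the original-spectra branch performs almost as well as
  the MSC branch, and which of the two maps more consistently varies
  with the scene draw. Field imagery, where specular effects are
  pixel-local and non-affine, is where MSC's advantage is expected to be
  systematic.
* PLSR, being linear, has zero aggregation bias when a uniform leaf's
  pixels are averaged; SVR's ε-tube (≈1.3 µg/cm² on the default Chl
  scale) introduces a small prediction bias that is visible precisely
  because the synthetic scenes are otherwise noiseless.
* The reflectance law is deterministic given the pigments: model
  accuracies on synthetic scenes are upper bounds, not forecasts, for
  field performance.

## A minimal session

```{r example}
library(leafpigmentr)

res <- run_pipeline(scene_config(), target = "chl_ab",
                    preprocess = "msc", select = "sfs",
                    select_learner = "svm_rbf", model = "svr_rbf",
                    map = TRUE, seed = 1)
res$selection   # chosen variable subset and RMSE curve
res$report      # LOOCV R2 / RMSE
plot(res$report)
plot(res$layers)
```
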