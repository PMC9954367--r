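---
title: "Mapping highly cellular tumor subregions from T2-weighted radiomics"
author: "heteromap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping highly cellular tumor subregions from T2-weighted radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In high-grade ovarian epithelial cancer, regions of high cellularity inside
a tumor restrict water diffusion and therefore show low apparent diffusion
coefficient (ADC) values on diffusion-weighted MRI (DWI). The clinical
convention adopted here calls a voxel *highly cellular* when its ADC lies
below 0.85 x 10^-3 mm^2/s. `heteromap` implements an automated pipeline
that learns to predict this ADC-defined class from T2-weighted image
appearance alone, so that a cellularity map can be produced for the T2
volume with the ADC map serving only as the reference standard:

1. **Registration** of the DWI series and the ADC map to the T2-weighted
   reference (affine by Mattes mutual information under Downhill Simplex,
   then Demons deformable refinement).
2. **Segmentation** of the tumor on the b = 1200 s/mm^2 DWI volume by
   K-means clustering (tumor is hyperintense at high b).
3. **Labeling** of tumor voxels by the ADC cut-off ("golden standard").
4. **Feature extraction**: per-pixel radiomic features from the T2 region
   of interest — a filter bank plus first-order and texture-matrix
   statistics (GLCM, GLRLM, GLSZM, GLDM, NGTDM).
5. **Feature selection** by recursive feature elimination with grouped
   cross-validation (RFE-CV).
6. **Classification** of tumor pixels, in blocks of 400, by a linear SVM
   or an SGD-trained linear model, evaluated leave-one-patient-out (LOPO).

Patient data of this kind cannot be redistributed, so the package ships a
synthetic phantom generator with known ground truth; every stage is
validated against phantoms, and the end-to-end experiment is a scaled-down
synthetic analogue of a small multi-patient clinical study.

## The phantom generator

`phantomSpec()` describes a pelvic-MRI-like study on a 48 x 48 x 12 grid
with 2 x 2 x 4 mm voxels (a small field of view at clinical resolution).
An ellipsoidal tumor (default radii 24/15/12 mm) is split into a low-ADC
(highly cellular) and a high-ADC subregion by thresholding a smooth random
field at the configured volume fraction (default 45% low-ADC), giving
spatially coherent subregions of ~10 mm scale. Per-voxel signal follows
the monoexponential diffusion model S(b) = S0 exp(-b ADC) at b = 0, 600,
1200 s/mm^2, with ADC 0.65/1.05/1.6 x 10^-3 mm^2/s in the low-ADC
subregion, high-ADC subregion and background. The T2 volume has distinct
subregion means (45 vs 70 against background 25) and, crucially,
subregion-specific *texture*: spatially correlated fluctuations whose
amplitude and correlation length differ between the subregions, so that
T2-derived texture features can in principle carry the cellularity signal.
Noise is additive Gaussian (sd 1.5) — the pipeline never assumes a noise
law, so the simpler model is preferred over Rician.

Two design points deserve emphasis:

* **Shared background anatomy.** One smooth random field modulates both
  the background T2 intensity and the background baseline DWI signal.
  Real pelvic anatomy gives the two modalities spatially correlated
  background structure; without it (homogeneous background, near-circular
  tumor) in-plane rotation is essentially unidentifiable for any
  intensity-based registration metric and misalignment recovery cannot be
  assessed meaningfully.

* **Analytic misalignment.** `applyMisalignment()` does not interpolate
  the noisy grid volumes; it re-images the continuous phantom at rigidly
  (+ elastically) transformed coordinates and adds fresh acquisition noise
  from the same per-volume seeds. This is the physically correct model of
  a patient who moved between acquisitions, and it avoids half-voxel
  interpolation artifacts that would otherwise displace the registration
  optimum by up to ~2 mm along the 4 mm slice direction. A zero transform
  reproduces the input volumes exactly.

What the phantom does **not** emulate: coil/bias fields, Rician noise,
fat/water effects, anatomically realistic organ shapes, multi-focal
disease, or the nonlinear T2-vs-cellularity relations of real tissue.
Passing tests therefore demonstrate the correctness and internal
consistency of the pipeline under its stated assumptions — not clinical
performance.

## Registration choices

The affine stage maximizes a Mattes-style mutual information: samples are
drawn once (deterministically from the metric seed), interpolated
linearly, and accumulated into a 32 x 32 joint histogram with linear
partial-volume (Parzen) weighting. Two details matter in practice:

* the MI is weighted by the fraction of samples landing inside both
  volumes, with a soft (one-voxel) fade at the boundary — otherwise the
  optimizer can inflate the raw MI simply by pushing samples off the
  grid, and hard overlap counting makes the objective discontinuous;
* plain hard-binned MI is piecewise constant at sub-voxel scales, which
  collapses a Nelder-Mead simplex on a plateau far from the optimum.
  (`mattesMutualInformation()`, the standalone metric, still reports the
  classic hard-binned estimate, for which identical images attain exactly
  their marginal entropy.)

Optimization runs Downhill Simplex (Nelder-Mead) from a moments
(intensity-centroid) initialization, with a coarse multi-start over
in-plane rotation, shrinking-scale restarts and a BFGS polish; defaults
are maxit 1000, relative tolerance 1e-7, and a 100% metric sampling
fraction. These are deliberately heavier than a minimal configuration:
at these volume sizes a full metric evaluation costs milliseconds, and
sub-voxel (<1 mm / <1 degree) recovery needs both the full sample budget
and the polish. On 10 seeded phantoms with rigid offsets up to 10 mm /
10 degrees, the affine stage recovers translation and rotation to well
under 1 mm / 1 degree median error (see the test suite).

The Demons stage refines the affine result with a dense displacement
field: the classic intensity-difference force along the fixed-image
gradient, Gaussian smoothing of the field each iteration, displacement
updates capped at one voxel, and best-field-so-far iteration that stops
after five consecutive non-improving steps — the reported trace contains
accepted (monotonically improving) steps only. On mono-modal pairs with
smooth synthetic warps the default configuration removes more than 80% of
the pre-warp RMS difference.

Cross-modality is the hard part: T2 and DWI intensities are not related
by any single monotone mapping (the highly cellular subregion is
DWI-bright but T2-darker than the cystic subregion), so Demons runs on
histogram-matched intensities *and is deliberately bounded* in
`alignStudy()` (3 iterations, 12 mm field smoothing). An unbounded
cross-modal Demons reduces its own matched-intensity RMS while visibly
*damaging* true alignment — it "fixes" intensity disagreements that are
not geometric. The bounded configuration contributes a small, safe
elastic correction after the affine stage; the full-strength defaults
remain available through `demonsConfig()` for mono-modal problems.

`alignStudy()` registers the b = 1200 volume to T2 once and applies the
composite transform identically to every b-value volume and to the ADC
map, which share the DWI frame. Resampling is trilinear onto the T2 grid
(transforms map fixed coordinates to moving coordinates), clamped at the
volume edge so near-identity transforms cannot introduce artificial zero
borders.

## Segmentation and labeling

K-means (k = 2, Lloyd iterations) on the b = 1200 intensities separates
the hyperintense tumor from background; initial centres sit at evenly
spaced intensity quantiles, which makes the clustering deterministic —
for one-dimensional intensity data this is at least as robust as a
randomized k-means++ start and removes a needless source of run-to-run
variation. The tumor cluster is reduced to its largest 6-connected 3D
component. The number of clusters and the cleanup are implementation
choices; phantom ground truth replaces the radiologists' visual
validation, with Dice >= 0.95 required at contrast-to-noise >= 5.

ADC labeling partitions the mask exactly: high (ADC below 0.85 x 10^-3
mm^2/s), low, optionally uncertain inside a configurable band (default
[0.85, 1.0] x 10^-3, used for the overlay figures only). Binary training
labels collapse uncertain into low; the band never enters training.
Voxel indices are 0-based externally with half-open bounding boxes.

## Per-pixel radiomics

The pipeline's contract is per-slice feature extraction feeding
pixel-by-pixel classification; the reconciliation implemented here gives
every tumor pixel
(1) the response of each filter-bank image at that pixel — original,
stationary single-level Coiflet-1 wavelet subbands (LL/LH/HL/HH),
Laplacian-of-Gaussian at 1/2/3 mm, square, square root, logarithm
(log(|x|+1)), exponential, gradient magnitude, and local binary pattern
codes (8 neighbours, radius 1), with the intensity transforms rescaled to
the original range so a zero image never yields NaN —
(2) first-order and GLCM/GLRLM/GLSZM/GLDM/NGTDM statistics computed in a
5 x 5 sliding window intersected with the mask, on a 32-level equal-width
discretization of the ROI, and
(3) per-slice 2D shape descriptors broadcast to the slice's pixels.
Texture conventions: GLCM distance 1 with 4 angles, symmetric,
angle-averaged; GLRLM over 4 directions; GLSZM zones 8-connected; GLDM
with Chebyshev distance 1 and tolerance 0; NGTDM with distance 1 and
coarseness 1/(1e-6 + sum p_i s_i). Every texture feature is verified to
1e-10 against independent brute-force enumeration oracles on small
images.

The window side is a genuine design choice: it must be large enough for
stable texture statistics yet small relative to the subregion scale, or
windows straddle subregion boundaries and blur the very contrast being
predicted. At the phantom's 2 mm in-plane resolution a 5-pixel (10 mm)
window matches the ~10 mm subregion correlation length and clearly
outperforms wider windows on held-out cases; `featureConfig(window=)`
exposes it for data at other resolutions.

Rows are ordered deterministically (slice, row, column) and chunked into
blocks of 400 pixels, the unit in which new cases are classified.
Windows with fewer than 2 masked pixels are dropped (counted and logged);
degenerate texture windows (no co-occurring pairs) contribute zero-valued
features rather than missing values, so the matrix is always finite.
The feature set (~115 columns) covers every family with the counts the
radiomics literature standardizes on: 19 first-order, 24 GLCM, 16 GLRLM,
16 GLSZM, 14 GLDM and 5 NGTDM features, plus the filter-bank responses
and shape descriptors.

## Selection and classification

RFE fits a weighted linear estimator on standardized features (training
statistics only), removes the 10% of remaining features with the
smallest absolute weights, and records mean cross-validated balanced
accuracy at each size; folds are grouped by case so pixels of one
patient never straddle train and validation (pixel-level folding would
leak spatial correlation). The selected size maximizes the CV score,
preferring the smaller subset on exact ties. During selection the rows
may be capped (default 1200, stratified by case and label) — selection
needs ranking stability, not every pixel.

Both estimators handle class imbalance with inverse-frequency class
weights and share an average-loss convention: the SVM soft-margin penalty
is normalized by the training-set size (reference 1000 rows), which makes
the decision function invariant under duplication of the training set and
keeps it consistent with the SGD objective (hinge loss, L2 1e-4,
mini-batches of 32, 100 epochs, inverse-scaling learning rate
eta0 / t^0.25). Everything is deterministic under the master seed: the
SVM because libsvm is deterministic (tolerance tightened to 1e-6), the
SGD through seeded shuffling.

Ten-fold cross-validation stratifies by case and falls back to the
largest feasible fold count (with a warning) when fewer than ten cases
are available. LOPO evaluation holds out one case at a time, reruns
constant-feature removal and RFE-CV on the remaining cases only, trains
both estimator kinds on the selected subset and scores the held-out
pixels against their ADC-derived labels; per-case accuracy, balanced
accuracy, sensitivity and specificity are reported with cohort averages
and standard deviations. Undefined metrics (zero denominators, e.g. a
tumor with only high-cellularity pixels) are reported missing and
excluded from averages with a note.

## Problem sizes and determinism

The shipped experiments use 48 x 48 x 12 phantoms (~1000-1700 tumor
pixels per case), an 8-case cohort for the LOPO study, 10 phantoms for
registration recovery and 4 for the acceptance script's registration
block. These sizes were chosen so the full suite runs comfortably on a
single CPU while keeping every stage statistically meaningful (3 blocks
of 400 pixels per case, ~9000 LOPO pixels). Determinism is exercised by
re-processing cases bit-identically and re-running the LOPO stage
bit-identically from the same feature matrices.

Registration quality in the end-to-end experiments is measured by
re-imaging the noiseless phantom through the composed
(estimated-then-true) transform: RMS differences computed on noisy or
interpolated volumes are floored by acquisition noise and resampling
blur (a ratio of ~0.6 even for sub-millimetre alignment) and do not
measure alignment; the analytic composition does.

## Known limitations

* Cross-modal Demons is intentionally conservative; on data where T2 and
  DWI intensities relate monotonically it underuses its potential.
* The affine metric assumes axis-aligned grids with a shared field of
  view; oblique acquisitions would need a full orientation matrix.
* Texture matrices are 2D (per slice), matching the per-slice extraction
  contract; 3D texture is out of scope.
* The per-pixel label standard is itself imperfect wherever registration
  residual moves the ADC subregion boundary by a fraction of a voxel;
  phantom LOPO scores should be read against that ceiling (label-truth
  agreement ~0.89 under the default misalignment), exactly as clinical
  scores are capped by imperfect reference standards.
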