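---
title: "Methods: speckle-texture luster grading of pearl OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle-texture luster grading of pearl OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model in one paragraph

An OCT B-scan of a pearl shows a bright, curved nacre band over a dark
background. The band carries two kinds of speckle: stochastic speckle
(averaged away at acquisition) and *inherent* speckle, a repeatable
interference texture tied to the aragonite/conchiolin microstructure that
also determines perceptual luster. `pearloct` treats luster grading as a
texture-classification problem: locate a standardized 128×128 subsurface
patch, digitize its speckle with seven descriptor families into a fixed
237-element vector, and classify the vector into grades A–D with an SVM or
a random forest tuned by randomized search.

# Automated target location

**Background threshold.** The top 30 rows of a B-scan lie above any
physically plausible surface and sample pure background. Their mean μ and
*population* standard deviation σ define a hard threshold μ + 2σ:
`denoise()` zeroes every pixel at or below it. For rectified Gaussian
background noise this leaves under 5% of background pixels nonzero, which
the test suite verifies by Monte Carlo against the generator. We read the
threshold's second term as two standard deviations, not two variances:
adding a variance (gray²) to a mean (gray) is dimensionally inconsistent.

**Surface detection.** `detect_rough_edge()` runs a Canny detector
(Gaussian σ = 2 px; hysteresis thresholds at 1.0× and 0.5× the Otsu level
of the gradient-magnitude histogram; 8-connected hysteresis) and takes the
shallowest edge pixel per column. Columns without edges are recorded as
missing; more than 50% missing raises "surface not found". The Otsu-scaled
thresholds adapt to the strong band/background contrast without manual
tuning.

**Fit and flatten.** A pearl is locally a spherical cap, so the default
polynomial degree is 2 (configurable). Missing columns are excluded from
the least-squares fit and filled by the fitted polynomial. Flattening
shifts each column by the *integer* `round(target_row − fitted_edge)`:
integer shifts preserve the raw speckle pattern that the texture bank
measures, at the cost of ≤ 0.5 px of rounding jitter; interpolation would
smooth exactly the second-order statistics we classify on. On synthetic
parabolic surfaces the fitted edge stays within ~0.5 px of the true
surface and the post-shift surface spread is ~0.3 px (std). At very high
speckle contrast a few percent of columns' topmost Canny edge locks onto a
subsurface speckle grain instead of the surface; the pooled polynomial fit
absorbs these outliers, which is why residuals are assessed against the
fitted/true surface rather than per-column re-detection on hard cases.

**ROI.** The "middle upper part" of the flattened image is taken as the
laterally centered 128×128 patch whose top row sits `offset = 2` rows
below the flattened surface line (`target_row = 20` by default); both are
configurable. Two rows of standoff avoid the specular surface response
while staying in the strongest part of the band.

# The texture bank

Layout (names from `feature_names()`, families from `feature_families()`):
FD[1], GLCM[40+40], LBP[14+14], Gabor[40+40], HOG[9+9], LAWS[9+9],
CSAC[6+6] — 237 values. Within every family the means of all
combinations precede the standard deviations. Conventions that the
descriptors' published definitions leave open were fixed once and are
listed here so vectors are comparable across runs:

* **FD** — differential box counting over box sizes s ∈ {2,4,8,16,32,64};
  gray column height h = s·256/128; per-block count
  ⌈max/h⌉ − ⌈min/h⌉ + 1; FD is the slope of log N(s) on log(1/s).
  A constant patch gives exactly 2 (one box per block at every scale).
* **GLCM** — 16 gray levels by uniform quantization of 0–255; symmetric,
  normalized matrices; statistics entropy (bits), energy (Σp²),
  correlation (0 for a constant image, resolving the 0/0 case), contrast
  ((i−j)² weighted). The "map" of a (statistic, distance) combination is
  its four per-angle values {0°, 45°, 90°, 135°}; the feature is that
  map's mean and (sample) SD. Ordering is statistic-major,
  distance-minor.
* **LBP** — plain (non-uniform) codes; neighbor 0 in the +column
  direction, ring walked with the −row (upward) neighbor first; bilinear
  interpolation for off-grid samples with offsets snapped to the grid
  within 1e−6; comparison `neighbor ≥ center − 1e−7 ⇒ bit 1`, so exact
  ties (a constant patch) set every bit. The whole ROI is one cell.
* **Gabor** — quadrature magnitude of even/odd pairs; envelope σ from a
  one-octave bandwidth (σ ≈ 0.56λ), isotropic envelope; the even kernel is
  DC-corrected so constant input gives (numerically) zero response;
  reflect padding. Orientations at multiples of 45° use `cospi`/`sinpi`,
  which makes a 90° ROI rotation permute orientation blocks exactly — a
  property test asserts this at 1e−8.
* **HOG** — central-difference gradients with replicated borders; unsigned
  orientations folded to [0°, 180°); 9 bins of 20° with hard,
  magnitude-weighted assignment; 4×4 cells (1024 on a 128×128 ROI); a
  single block, no normalization — offsets in intensity cancel exactly.
* **LAWS** — ROI mean subtracted, then 5×5 outer-product kernels. The
  mirrored asymmetric pairs (L5E5/E5L5 …) are averaged as
  (|r₁| + |r₂|)/2; both the mean and the SD are taken on this
  texture-energy map, since the signed responses of mirrored kernels
  cancel structure that the energy retains.
* **CSAC** — for each 3×3 neighborhood with center-symmetric pairs
  (NW,SE), (N,S), (NE,SW), (W,E) and μ the mean of the 8 neighbors:
  SCOV = ¼Σ(xᵢ−μ)(xᵢ′−μ), VAR = ⅛Σ(xⱼ−μ)², SAC = SCOV/VAR (0 when
  VAR = 0), pair means mᵢ, WVAR = ¼Σ(xᵢ−mᵢ)², BVAR = ¼Σ(mᵢ−μ)²,
  SVR = BVAR/(WVAR + 1e−12). SAC and SVR are invariant under positive
  linear gray maps, which a test asserts on float input.

All four of GLCM, LBP, LAWS and CSAC are checked against independent
brute-force oracles (explicit double loops) on random 8×8 patches at
1e−9; FD against an explicit block-loop oracle.

# Grading

`luster_grader()` draws candidate configurations — SVM: kernel ∈
{radial, polynomial, sigmoid}, cost log-uniform on [1e−2, 1e2], γ
log-uniform on [1e−4, 1]; RFC: trees uniform on [5, 200], `mtry` uniform
on [1, 20] — scores each by mean accuracy under a stratified 5-fold CV
whose fold assignment is drawn once and shared, and refits the winner.
The SVM route z-scores features with training-fold statistics (the 237
features span four orders of magnitude; the small optimal γ regime only
makes sense on standardized inputs); scalers travel with the model. R's
`randomForest` splits on Gini only, so no split criterion is searched.
The default budget is 500 candidates (`search_space(iterations = )`); the
CLI exposes `--iterations` for exhaustive budgets. Ties in CV score keep
the earlier candidate, making the search deterministic given its seed.

Metrics are macro-averaged over the four grades with the 0/0 → 0
convention for never-predicted classes; accuracy is the confusion-matrix
trace ratio. `repeated_experiment()` runs independent stratified splits
(per-class round-half-up of 0.8·n, so 116 balanced samples give 92/24)
and reports max/min/avg per metric for train and test.

`pca_reduce()` standardizes with training statistics and fits components
on the training half only — fitting on all samples before splitting would
leak test structure into the projection. `sequential_select()` is
standard backward elimination: the step removes the feature whose removal
maximizes CV accuracy (ties toward the lowest index), with
hyperparameters frozen (pass a tuned grader's `best_params`) and one
shared fold assignment, until round(fraction·p) remain.

# The synthetic generator

`generate_bscan()` emulates what the texture bank needs from a pearl
B-scan, not OCT physics:

* geometry — a parabolic surface `apex + curvature·(c − w/2)²`
  (default apex 140 px, curvature 1.2e−3 px⁻¹: ~79 px of sag over a
  512-px scan, a plausible pearl cap), a 220 px band, 8-bit output;
* background — rectified Gaussian noise (σ = 4 gray levels);
* band — mean intensity 180 decaying as exp(−0.008·depth), multiplied by
  a correlated unit-mean speckle field.

The speckle field is exp(G) with G a Gaussian field low-pass filtered per
axis (filter σ = L/2 gives an autocorrelation 1/e half-width of L) and
rescaled so sd/mean equals the requested contrast exactly in expectation.
A lognormal field was chosen over filtered gamma noise because the
renormalization required after filtering stays positive at any contrast;
an additively renormalized field clips at zero around contrast 0.8 and
biases the realized contrast by ~20%, which would defeat the generator's
own contrast-recovery test (15% relative tolerance, verified at a mean
gray level where 8-bit clipping is negligible).

The four grades are separated primarily by a 2× speckle-contrast ladder
(A: 0.10, B: 0.20, C: 0.40, D: 0.80) with correlation lengths growing
from (1.0, 1.5) to (2.0, 4.5) px (axial, lateral) — statistically
separable second-order structure over overlapping pixel histograms.
This mapping is a *stand-in*: no quantitative link between luster grade
and speckle statistics is claimed for real nacre, so classifier accuracy
on synthetic data demonstrates pipeline correctness (parameter recovery),
not gemological validity. The generator also omits real-data features —
depth-dependent speckle decorrelation, nucleus/nacre interfaces, surface
defects, scan-to-scan jitter — so passing tests bound implementation
error, not robustness to such structure.

# Problem sizes and budgets

Tests and the acceptance script run the study-scale protocol — 116 images
(29 per grade), 10 repeated 92/24 splits — with a reduced search budget of
15 candidates per run; on the well-separated default classes the selected
models are insensitive to the budget, and the package default remains 500.
Oracle-equivalence tests use 8×8 patches where exhaustive double loops
are exact and cheap; backward-elimination properties are exercised on
tables of 3–24 features, since the greedy path over 237 features costs
O(p²) CV evaluations and demonstrates nothing further about correctness.

# Known limitations

* The class-to-speckle mapping is invented; real luster grading requires
  the proprietary image corpus this package deliberately does not need.
* Single-surface segmentation only: no nucleus/nacre interface, no defect
  detection.
* The Canny-topmost-pixel rough edge degrades per column at extreme
  speckle contrast (the polynomial fit compensates; see above).
* `randomForest` restricts the split criterion to Gini.
* Backward elimination at full 237-feature scale is computationally
  expensive by construction; use a frozen-parameter SVM and expect long
  runtimes, or select on a family-subsampled table first.
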