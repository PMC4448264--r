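---
title: "Quantifying tumor-nest morphology in H&E images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-nest morphology in H&E images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestquant)
```

## The problem

In invasive ductal carcinoma of the breast, malignant epithelial cells grow
as connected clusters — tumor nests — embedded in supportive stroma that
contains fibroblasts, vessels and infiltrating immune cells. The
architecture of the nests (their number, size, boundary complexity) and the
cytology of the cancer-cell nuclei carry prognostic information that routine
grading summarizes only coarsely and with substantial inter-observer
variability. `nestquant` implements a computer-aided analysis of
hematoxylin–eosin (H&E) stained fields that turns this morphology into
numbers: it segments nests vs stroma and individual nuclei, measures a
730-parameter feature catalog per image, compresses selected parameters into
composite prognostic scores, and relates them to disease-free survival
through cutpoint-based risk grouping, Kaplan–Meier/log-rank analysis, Cox
regression and ROC curves.

Because no patient images or outcome data are distributed with this package,
a synthetic-data module generates H&E-like fields with exact ground truth
and survival cohorts with known effect sizes. Every stage of the pipeline is
tested against those generators.

## Pipeline stages

### Preprocessing

Three deterministic steps precede segmentation: a 3×3 median filter
(edge-replicated borders; implemented as a vectorized 9-element exchange
network), per-channel percentile contrast stretching (defaults 1st → 0 and
99th → 255), and optional Reinhard-style color normalization — per-channel
mean/sd matching in CIE Lab against a reference image. Stain separation uses
Beer–Lambert color deconvolution, `OD = -log10(I/255)` projected onto the
standard published H&E unit vectors (hematoxylin ≈ (0.65, 0.70, 0.29),
eosin ≈ (0.07, 0.99, 0.11), residual by cross product). Deconvolution and
reconstruction round-trip within 2 intensity levels on noise-free synthetic
renders.

Percentile stretching is applied per channel and therefore distorts the
strict linearity of the Beer–Lambert model; downstream thresholds are chosen
robustly for that reason (see the marker depth below).

### Nuclei segmentation

A marker-controlled watershed on the hematoxylin optical density (OD):

1. **Mask.** Otsu threshold on the OD histogram, morphological opening with
   a disk of radius 2 px, hole filling.
2. **Markers.** Regional maxima of the Gaussian-smoothed OD (σ = 2 px)
   inside the mask, after suppressing maxima shallower than a depth `h`
   (equivalently, regional minima of the inverted map). The default
   `h` is 10% of the *robust* OD spread — the 10th-to-90th percentile range
   of the smoothed OD inside the mask — rather than the full min–max range:
   contrast stretching maps the darkest pixel cores to extreme OD values
   (≈ 4.6) that double the raw range, and a depth tied to it merges touching
   nuclei. Each surviving maximum is reduced to its peak pixel.
3. **Growth.** Seeded region growing over the OD landscape assigns every
   mask pixel to exactly one marker; mask components containing no marker
   are returned whole and flagged `unseeded`.
4. **Spurious-region removal.** Survivors must satisfy
   area ∈ [30, 3000] px², solidity ≥ 0.7 and mean boundary gradient
   ≥ 5 intensity/px (gradient of the transmission image along the region
   boundary — the realization of the "boundary saliency" criterion). The
   thresholds were fixed once against the synthetic generator and are
   exposed through `spurious_rules()`.

Solidity uses the convex hull of pixel *corners* so thin regions get a
positive hull area; note a perfectly round digital disk then has solidity
≈ 0.9, which the default gate comfortably accepts.

### Tumor-nest vs stroma segmentation

A pixel-wise SVM (RBF kernel, `C = 1`, `gamma = 1/15`, features
z-standardized with training statistics) on a 15-dimensional per-pixel
descriptor over a 9 px window: per-channel local homogeneity
`1 − sd_w/127.5`, raw R, G, B, an 8-bin local-binary-pattern histogram
(fraction of window pixels whose k-th neighbor exceeds the center) and the
local gray-level variance. Any fixed-length texture descriptor could be
substituted; this one is fast, deterministic, and sufficient for the
synthetic appearance model. Training pixels are drawn without replacement
from labeled regions (in production from expert annotation; in testing from
ground truth). Post-processing is a deterministic stand-in for interactive
expert correction: morphological closing (disk radius 3 px), removal of nest
components and stroma holes below 500 px², plus an optional correction mask
that overrides the result wherever it is not `NA`.

### Nucleus classification

A nucleus whose centroid falls inside a nest is epithelial; stromal nuclei
split into round (immune cells; eccentricity < 0.8) and non-round
(fibroblastic/vascular, pooled). Membership by centroid rather than area
overlap is deterministic and matches the pseudo-color rendering
(`render_pseudocolor()`: nest yellow, stroma black, epithelial red,
non-round green, round purple). The 0.8 eccentricity default is a design
choice — no numeric shape threshold is published; the monotonicity property
(raising the threshold never decreases the round count) is tested.

### The 730-parameter catalog

The full parameter list of the original analysis is not publicly available,
so the catalog is *constructive*: a documented scheme that reproduces the
printed level counts exactly and guarantees that every published parameter
exists under a canonical name (`catalog_aliases()`):

* **Pixel level, 400** = 4 regions (image, nest, stroma, nuclei mask) × 10
  channels (R, G, B; H, S, V; Lab lightness and chroma; hematoxylin and
  eosin OD) × 10 statistics (mean, sd, min, max, median, p10, p90,
  skewness, kurtosis, 64-bin histogram entropy). Degenerate regions give
  `NA`; zero-variance vectors define skewness/kurtosis as 0.
* **Object level, 314** = 4 object classes (nests, epithelial, stromal
  round, stromal non-round) × 11 per-object descriptors (area, perimeter,
  eccentricity, solidity, circularity, major/minor axis, extent, boundary
  gradient, Feret diameter, orientation) × 7 aggregates (count, sum, mean,
  population variance, min, max, median) = 308, plus 6 topological
  parameters: nest-boundary fractal dimension, Delaunay triangle-area sum /
  edge mean / edge variance over epithelial centroids, the stromal cell
  structure parameter, and the mean nearest-neighbor distance over all
  nuclei.
* **Semantic level, 16** named ratios and densities, including every
  published semantic parameter (TNs cell density, stromal non-round cell
  density, nuclei-area/nest-area ratio, nest-area/perimeter ratio) plus
  nest/stroma area ratio, stromal round cell density,
  nuclei/cytoplasm ratio and further compartment fractions.

Interpretive choices, flagged as such: the *stromal cell structure
parameter* is realized as the mean Delaunay edge length over stromal
non-round nucleus centroids (px) — consistent in spirit and scale with its
published cutpoints (26.21/32.57) but not derivable exactly from the source;
Delaunay statistics are computed per image, not per nest; all areas and
densities are in pixel units. Variances are population variances. The
fractal dimension uses box sizes 2, 4, …, `min(H, W)/4` (powers of two) over
the 8-connected nest boundary; the estimate is the negative least-squares
slope of `log N(s)` vs `log s`, clamped to [0, 2].

Images aggregate to patients by the per-feature mean over the patient's
images, ignoring missing values — the simplest defensible rule where no
aggregation is published.

Pixel-level parameters are computed but excluded from survival modeling,
mirroring the original analysis (they are the least interpretable).

### Composite features

Two composite scores are shipped with their published coefficients applied
to z-standardized inputs:

* TNs feature = 0.260·(nest count) + 0.107·(perimeter sum) − 0.281·(area
  mean) − 0.272·(area variance) − 0.268·(area/perimeter ratio);
* TNs cell nuclei feature = 0.048·(eccentricity max) + 0.482·(nuclei area
  mean) + 0.478·(nuclei area variance) + 0.246·(nuclei/nest area ratio).

Whether the original coefficients apply to raw or standardized parameters is
not stated; standardized inputs are the default because the published
three-level cutpoints of the scores (−1.28/−0.09 and 1.60/2.94) are on
roughly centered scales, and `composite_spec(standardize_inputs = FALSE)`
provides the raw mode. `fit_pca_composites()` re-derives data-driven
composites as the first principal component per block (unit-norm loadings,
sign fixed so the largest-magnitude loading is positive).

### Survival analysis

`find_cutpoints()` converts a continuous feature into three risk groups by
exhaustive search over all ordered pairs of cutpoints at observed-value
midpoints, maximizing the 3-group log-rank chi-square subject to a minimum
group share (default 10%). This mirrors the X-tile-style optimization used
in practice — and inherits its optimism: the selected statistic is a maximum
over many correlated tests, so its naive chi-square p-value rejects a true
null far more often than 5%. The package documents rather than hides this:
the test suite demonstrates the inflation by simulation, and the returned
object carries both `p_value` (naive) and `p_corrected` (a
Miller–Siegmund-style correction for maximal selection; approximate for the
two-cutpoint case, never smaller than the naive value). The search loop uses
an in-package vectorized log-rank statistic that the tests pin against
`survival::survdiff` to 1e-10; `km_logrank()` itself delegates to
`survfit`/`survdiff`. Cox models use `survival::coxph` with Efron tie
handling and Wald 95% intervals; non-convergence and separation are flagged,
never returned silently. ROC AUC is the trapezoidal/concordance estimate
with a DeLong interval (`pROC`). NPI = 0.2·size(cm) + node stage + grade,
with the conventional ≤2.8 / 2.8–4.4 / >4.4 categories. Two-sided α = 0.05
with no multiple-testing correction is the default reporting convention,
matching the procedure being reproduced; `p.adjust` can of course be applied
to any tidy output.

## The synthetic generators

`image_scenario()` renders fields at the pixel scale of the study material
(200×, 1360 × 1024 frames): epithelial nuclei of ~200 px² packed in nests at
~0.0013 /px², nests of ~12,000 px² covering roughly half the field, stromal
non-round density ~0.00045 /px² — all consistent with the published
three-level cutpoints of the corresponding parameters. The default field is
544 × 416 px, a sub-field at the same scale with the nest count scaled by
area (≈ 11), which keeps a full scenario run in seconds. Where no value is
published (stromal round density 0.0004 /px², stain intensities, noise
level) values were chosen once for testability and realism and are exposed
as scenario fields.

Rendering choices that matter for testing:

* Nests are unions of 1–4 overlapping ellipses with sinusoidally jittered
  boundaries, so nest perimeters are irregular and the boundary fractal
  dimension is non-trivial.
* Nuclei are hematoxylin OD blobs converted to RGB by Beer–Lambert with the
  packaged stain matrix, so color deconvolution is exactly invertible up to
  noise. The OD profile is a plateau with a sigmoid falloff that crosses
  half-maximum exactly at the ground-truth ellipse boundary, so threshold
  segmentation recovers the true area rather than a profile-dependent
  fraction of it.
* Nuclei are solid bodies: centers are rejected while they would
  interpenetrate an already placed nucleus (minimum spacing 0.95× the sum of
  equivalent radii, relaxed progressively so the requested count is always
  placed). Without this, a substantial fraction of nuclei have no intensity
  peak of their own and no OD-based marker scheme can resolve them.
  Requested densities that cannot physically fit (> 80% packing) raise
  `"infeasible density"`.
* The only corruptions are Gaussian pixel noise and a linear illumination
  ramp — enough to exercise preprocessing, deliberately not a model of
  staining artifacts, necrosis or out-of-focus blur.

`cohort_scenario()` draws exponential event times with hazard
`baseline_hazard · exp(Σ β·feature)` — constant baseline hazard
`log(2)/50.1` per month (the published median disease-free survival under
the null), administrative censoring at 96 months (8-year follow-up), and
random exponential censoring calibrated so a fraction `censor_rate` (default
0.339, the published censoring share) of subjects are lost before their
event under the null. Clinical covariates are drawn from the published
marginal frequencies (grade 8.7/75.7/15.6%, ER+ 45.7%, HER2+ 36.1%) and are
independent of the generated features. The exponential model has closed-form
survival, which the tests exploit: the null Kaplan–Meier curve must track
`exp(−λt)` within binomial error, and Cox fits must recover the generating
log-hazard.

**What passing tests do and do not show.** The generators produce separable,
moderately noisy scenes: nests differ from stroma in nuclear packing and
cytoplasmic tint, nuclei are well-formed ellipses. Success on them
demonstrates that the algorithms are implemented correctly and are
internally consistent with their ground truth; it does not demonstrate
robustness to real H&E variability — overlapping nuclei, stain batch
effects, necrosis, tissue folds — and no claim of clinical performance is
made or reproduced here.

## Problem sizes

The shipped test suite and acceptance script use, by design: per-module
scenes of 128 × 96 to 256 × 192 px; the full default 544 × 416 scenario once
for segmentation recovery; Cox recovery with 50 cohorts of n = 1000;
cutpoint-oracle comparisons at n ≤ 60 (the exhaustive reference search is
quadratic in distinct values); and a 6-patient end-to-end run executed twice
for determinism, plus one 20-patient run. These sizes make the whole suite
run in about a minute while leaving every statistical check adequately
powered.

## Known limitations

* The texture descriptor and color-normalization method are reasonable
  stand-ins for procedures the source describes only by citation; both are
  replaceable behind the same interfaces.
* The stromal cell structure parameter is an interpretation (see above).
* The cutpoint search reproduces an optimistic procedure; `p_corrected` is
  approximate for two cutpoints (derived from the single-cutpoint maximal
  statistic bound) and should be read as an inequality, not an exact level.
* Watershed splitting degrades for deeply overlapping nuclei; the detection
  guarantees are stated for solid (non-interpenetrating) nuclei.
* Whole-slide images, multispectral stacks and batch harmonization across
  scanners are out of scope.
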