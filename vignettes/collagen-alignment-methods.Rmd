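---
title: "Quantifying stromal collagen alignment and its prognostic value: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stromal collagen alignment and its prognostic value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collalign)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is dominated by a dense desmoplastic
stroma rich in fibrillar collagen. Second-harmonic generation (SHG)
microscopy images fibrillar collagen without labels, and the *organisation*
of those fibers — in particular how strongly they align around the malignant
epithelium — carries prognostic information. `collalign` implements the full
analysis chain needed to test that hypothesis on tissue-microarray material:
fiber segmentation and an alignment statistic on SHG-style images,
registration of brightfield histology onto SHG so pathologist-drawn regions
of interest (ROIs) can be transferred, stain quantification for
immunohistochemistry, and cohort-level survival statistics with an
alignment cutoff. Because no patient imaging data are distributed, a
synthetic-data module generates every input with known ground truth; all
tests and the acceptance study run against those generators.

## The alignment statistic

Fiber orientation is *axial*: a fiber at angle $\theta$ is the same fiber at
$\theta + 180^\circ$. The standard circular-statistics treatment doubles the
angles, so the alignment of $n$ fibers with orientations $\theta_i \in
[0^\circ, 180^\circ)$ is the mean resultant vector length

$$R \;=\; \left| \frac{1}{n} \sum_{i=1}^n e^{\,2 i \theta_i} \right|
\;=\; \sqrt{\Big(\tfrac1n\sum_i \cos 2\theta_i\Big)^2 +
            \Big(\tfrac1n\sum_i \sin 2\theta_i\Big)^2} .$$

$R = 1$ when all fibers share one direction and $R \to 0$ for uniformly
distributed orientations. Each fiber contributes one angle regardless of its
length, matching the per-fiber output of curvelet/FIRE-style fiber trackers;
length weighting and the undoubled variant are available behind flags for
sensitivity analysis. Numerically the angles are first rotated by the first
element (the statistic is rotation invariant), which makes the degenerate
all-identical case evaluate to exactly 1.

```{r alignment}
alignment_score(rep(30, 100))
alignment_score(c(0, 90))     # orthogonal axial pair cancels
```

## Fiber extraction

The fiber segmenter is deliberately simple and fully specified: Gaussian
smoothing (`smoothing_scale`, default 1.5 px), Otsu thresholding of the
normalised image (or a fixed threshold), Zhang–Suen thinning to a one-pixel
skeleton, branch-point removal, and one orientation per remaining simple
path from the principal axis of its pixel coordinates. Path length is the
extent of the pixel cloud along that axis; segments shorter than
`min_length_px` (default 30) are dropped.

Two implementation details matter in practice. Branch points are detected by
the 8-neighbourhood *crossing number* (number of 0→1 transitions around the
pixel) rather than a raw neighbour count — a staircase corner on a diagonal
path has three neighbours but only two transitions, and treating it as a
junction shatters the skeleton. Second, the full 3×3 neighbourhood of each
branch point is cleared, because junctions between merged fibers are wider
than one pixel and single-pixel removal often leaves the arms connected.

This segmenter is a stand-in for dedicated fiber-tracking software, which
the upstream workflow treats as a black box. It recovers orientation well on
fields where fibers are resolvable; under heavy overlap (foreground coverage
beyond roughly 50%) merged bundles fragment and per-fiber counts drop, which
is why the synthetic test fields are generated at moderate densities.

## Synthetic data: what it emulates and what it does not

* **Fiber fields** (`make_fiber_image`): straight anti-aliased segments with
  axial von Mises orientations — $2\theta \sim \mathrm{vM}(2\mu, \kappa)$,
  sampled by the Best–Fisher rejection algorithm and halved; $\kappa = 0$ is
  uniform, $\kappa = \infty$ degenerate. Poisson shot noise and Gaussian
  background noise are configurable. Ground truth (every drawn angle and
  length) is returned, so the true $R$ is recomputable exactly. Curvature,
  fiber width variation and bundling are *not* modelled: the alignment
  statistic uses one angle per fiber, so straight segments exercise every
  code path that matters.
* **Brightfield pairs** (`make_he_pair`): collagen is rendered as eosin
  optical density at the SHG fiber locations, nuclei as hematoxylin disks,
  composed by the Beer–Lambert model
  $I = I_0\,10^{-C^\top V}$ and resampled so that the map taking the
  returned image onto the SHG frame equals a caller-chosen affine transform,
  which is stored for recovery tests. Real H&E has far richer texture; the
  pair shares the collagen structure with the SHG image by construction,
  which is precisely the property the registration step relies on.
* **IHC images** (`make_ihc_image`): an organic tissue mask from thresholded
  smoothed noise, each tissue pixel assigned DAB with the target probability
  at stain concentrations (0.5–1.0) well above the positivity threshold, so
  the realized positive fraction is recorded exactly.
* **Cohorts** (`make_cohort`): `round(frac_high * n)` patients (default 12%
  of 114) receive latent alignment above the 0.60 cutoff, the rest below,
  spanning the observed inter-patient range 0.29–0.71; each carries 2–4
  tumor cores (regions low_grade / high_grade / core / edge, plus a normal
  core with probability 0.73) with 1–2 ROIs per core and Gaussian
  within-patient dispersion (default sd 0.02 — no study constrains this, so
  it is an exposed parameter). Overall survival is exponential with hazard
  $h_0 \exp(\beta\,\mathbb{1}[\bar a_i \ge 0.60] + x_i^\top\gamma)$, where
  $h_0 = \log 2 / 26.9$ months and $\beta = \log 2.25$ by default, and the
  censoring time is exponential with rate $\lambda_i\,c/(1-c)$ so each
  patient is censored with probability exactly `censor_fraction` (default
  0.4). Covariate margins loosely follow the reference cohort (46% female,
  65% over 65, 71% T3/T4 and N1, 78% G2/G3, 25% R1, 61% adjuvant); their
  hazard effects default to zero and are settable per covariate.

Passing tests on these generators show the *pipeline* is correct — they do
not show that real PDAC stroma is segmented as cleanly, that real H&E/SHG
pairs share as much mutual structure, or that real survival is exponential.

## Registration

The brightfield-to-SHG registration is two-step. First, collagenous stroma
is extracted from the H&E image: a decorrelation stretch (channel covariance
whitened and re-expanded to a common sigma) followed by k-means clustering
of the stretched colours (k = 4 by default, 5 restarts under a fixed seed),
keeping the cluster whose mean colour, in optical density, is closest in
cosine distance to the eosin vector. Second, the lightly smoothed mask is
registered to the SHG image by maximising mutual information (MI, 32-bin
joint histogram, 20% pixel sampling at the finest level) over the six
parameters of an affine transform, in a 3-level Gaussian pyramid, with a
numerically estimated gradient and backtracking step halving
(`tol` $10^{-5}$ MI bits, 200 iterations per level).

Histogram MI over a handful of pose parameters has many shallow local
optima at coarse resolution, so before gradient ascent the coarsest level
runs an exhaustive sweep over translations (±24 px in steps of 4) jointly
with rotations (±12° in steps of 3°) and starts the ascent from the best
cell. Pose parameters are always expressed in finest-resolution pixel units
about the fixed-image centre, so no rescaling is needed between levels. If
the final MI does not beat the identity transform, the identity is returned
with a warning flag. On synthetic pairs this recovers translations up to
20 px, rotations up to 10° and anisotropic scales 0.95–1.05 to within a
pixel in roughly 19 of 20 seeded cases; the registration part of the
acceptance suite measures exactly that.

Serial-section registration (H&E to IHC) is the same routine run on tissue
masks; no separate algorithm is provided.

## Stain quantification

Optical density is $-\log_{10}(\max(I,1)/I_0)$ per channel ($I_0 = 255$
by default); concentrations come from inverting the 3×3 unit-OD stain
matrix, with negative values clipped to zero and counted. The round trip
(compose → OD → deconvolve) is exact to $10^{-6}$ in floating point and
within 0.02 after 8-bit quantisation for concentrations up to 1.0 — beyond
that, transmitted intensities fall low enough that one 8-bit step exceeds
the bound, which is a physical property of the encoding, not a tunable.

A pixel is DAB-positive when its DAB concentration is at least
`od_threshold` (default 0.15 — the plugin-based workflow this mirrors never
states one, so it is exposed as configuration) and exceeds hematoxylin;
positivity is DAB/(DAB + hematoxylin) with background excluded. The ordinal
stromal scale maps fractions below 10% to 1, 10–50% inclusive to 2 (the
source scale is printed as "<10%", "10–50%", ">50%", so both boundaries are
read into the middle bin), above 50% to 3; reviewer scores are averaged.
EMT is scored as the fraction of epithelial cells in a per-cell table with
both marker intensities at or above their thresholds — upstream spectral
unmixing and cell segmentation are assumed done and are out of scope.

## Cohort statistics

A patient's alignment is the unweighted mean of all tumor-region ROI values
(normal-region ROIs ignored); patients with fewer than two tumor cores are
excluded with a recorded reason. Whether ROIs should instead be averaged
per core first is ambiguous in the source workflow; direct ROI averaging is
the default and the alternative is a one-line change at the call site.
Dichotomisation puts the cutoff value itself in the high group (≥ 0.60).

The training-cohort cutpoint scan evaluates the two-group log-rank
chi-square at every unique observed value inside the 10th–90th percentile
window (or a 41-point percentile grid), subject to a minimum group size of
max(5, 10% of the cohort), and returns the argmax. Because a maximally
selected statistic is optimistic, the scan can also report a
permutation-adjusted p (1,000 label permutations of the maximal statistic
by default); the Monte-Carlo cross-validation of the original cutpoint
software is out of scope and the permutation guard is a stated substitute,
not a reproduction.

A caveat worth stating plainly: with 70 patients of whom ~12% are high, a
hazard ratio of 2.25 and ~40% censoring, the log-rank noncentrality at the
true split is about 3 — the same order as the selection optimism of the
maximum over ~50 correlated candidates — so the scan recovers the true
threshold within one grid step only about half the time. Threshold
*recovery* at those sample sizes is unreliable no matter the
implementation; the scan's argmax converges as the cohort grows (tested
over n = 70/200/1000), and simulations show even a HR of 4 with no
censoring only reaches ~84% recovery at n = 70.

Kaplan–Meier, log-rank and Cox fits are computed by the survival package
(Efron ties by default; the duplication-invariance folk check applies to
Breslow ties and is tested there). Wald 95% intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. Backward selection starts from the
candidates with univariate Cox p < 0.25 plus the forced clinical covariates
(pT, pN, margin, grade), repeatedly dropping the worst non-forced covariate
at or above the threshold; forced covariates are never dropped. Fisher
exact tests (association of the alignment group with clinicopathological
2×2 tables, unknown-category rows excluded), Spearman rank correlations and
Shapiro–Wilk-reported Mann–Whitney/Kruskal–Wallis comparisons complete the
toolbox. All p-values are two-sided with significance at 0.05.

## Numerical and design choices

* Coordinates are 0-based `(x, y)` pixels, x right, y down; transforms are
  2×3 `[A | t]` acting on column vectors, moving → fixed.
* ROIs are half-open squares `[x, x+side) × [y, y+side)`; the side is
  `round(400 / pixel_size_um)` px for the 400 µm annotation convention.
  Transferred ROIs re-impose an axis-aligned square with side the mean of
  the mapped bounding-box extents, clipped and flagged at image borders.
* Tile stitching places tiles at `round(size · (1 − overlap))` steps and
  blends overlaps by linear feathering with weight normalisation, so a
  constant field stitches to a constant and a cut-up image round-trips to
  within interpolation error.
* K-means uses multiple random restarts under a fixed seed rather than a
  k-means++ initialisation; determinism under the seed is the contract.
* Degenerate inputs: empty angle lists, blank images and all-stained-free
  IHC give flagged-undefined results, not errors; constant images make the
  decorrelation stretch a warning no-op; a singular stain matrix or affine
  linear part is an error.
* Test and acceptance problem sizes — 128–192 px images, 20 registration
  cases, 500 simulated cohorts of 114 patients, 100 training scans of 70 —
  were chosen as the smallest sizes at which the measured quantities
  stabilise.

## Limitations

* The fiber segmenter is not a curvelet/FIRE replacement: it reports no
  curvature, width or straightness, and fragments under heavy fiber
  overlap.
* Registration is affine only; deformable registration and whole-slide
  pyramid formats are out of scope.
* The survival generator uses exponential times and independent censoring;
  real cohorts violate both.
* Stain separation assumes the 3×3 OD model with known vectors; spectral
  unmixing beyond three channels and cross-slide stain normalisation are
  not attempted.
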