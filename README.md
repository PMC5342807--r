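# collalign

Quantification of stromal collagen fiber alignment in SHG-style microscopy
images, registration of brightfield histology onto SHG, stain positivity
scoring, and survival stratification of patient cohorts by an alignment
cutoff.

Pancreatic ductal adenocarcinoma (and several other solid tumors) remodels
its collagen-rich stroma, and the degree to which collagen fibers align
around malignant epithelium is a candidate prognostic marker. This package
is aimed at quantitative-pathology and biomedical-image-analysis groups who
want a tested, end-to-end reference implementation of that analysis: every
stage runs on synthetic data with known ground truth, so each claim the
pipeline makes is checkable.

## The statistic at the core

Fiber orientations are axial (θ ≡ θ + 180°). The collagen alignment of n
fibers with orientations θᵢ ∈ [0°, 180°) is the circular-statistics mean
resultant vector length on doubled angles,

    R = | (1/n) Σᵢ exp(2·i·θᵢ) |  ∈ [0, 1],

with R = 1 when all fibers share one direction and R ≈ 0 for uniform
orientations. Patients are scored by averaging R over all tumor-region ROIs
(with at least two tumor cores required), dichotomized at an alignment
cutoff of 0.60 discovered by a log-rank scan on a training cohort, and
compared by Kaplan–Meier/log-rank and Cox proportional-hazards models with
backward covariate selection.

## Worked example

```r
library(collalign)

## a synthetic SHG-like fiber field with known ground truth
f <- make_fiber_image(fiber_field_spec(n_fibers = 60, mean_angle = 30, kappa = 4,
                                       fiber_length_px = 40,
                                       image_size_px = c(128, 128), seed = 7))
true_alignment(f$fibers)            # 0.874  (exact recomputation from truth)

fs <- extract_fibers(f$image, min_length_px = 15)
nrow(fs)                            # 22 segments
alignment_score(fs$theta_deg)       # 0.933  (measured R of the same field)

## paired H&E image displaced by a known transform, recovered by registration
he <- make_he_pair(f$image, f$fibers, affine_translation(8, -5), seed = 8)
tf <- register_he_to_shg(he$rgb, f$image, seed = 9)
tf$m[, 3]                           # 8.27 -4.83  (truth: 8, -5)

## a 114-patient cohort with a hazard ratio of 2.25 built in
ch  <- make_cohort(cohort_spec(seed = 10))
grp <- dichotomize(ch$patients$alignment)        # 100 low / 14 high
logrank_test(ch$patients$os_months, ch$patients$event, grp)$p   # 0.032
cox_fit(data.frame(high = ch$patients$high_alignment),
        ch$patients$os_months, ch$patients$event)
#> Cox PH fit (efron ties), n = 114, events = 70
#>  term               hr          p
#>  high 2.14 (1.05-4.37) 0.0367
```

The Cox interval 1.05–4.37 brackets the generating hazard ratio 2.25; the
high-alignment group's Kaplan–Meier median OS (13.0 months vs 28.6 for the
low group on this seed) shows the built-in survival penalty. `run_demo()`
executes the whole chain — synthesis, stitching, registration, ROI
transfer, fiber and stain quantification, cutpoint discovery, KM/Cox — and
writes the tables, a JSON summary and a markdown report under an output
directory; a thin command-line wrapper lives at `inst/cli/collalign.R`.

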