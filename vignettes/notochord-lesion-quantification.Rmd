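---
title: "Quantifying notochord lesions along a fitted polynomial centerline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying notochord lesions along a fitted polynomial centerline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notoquant)
```

## The measurement problem

In larval zebrafish whose notochord cells express an oncogenic RAS
reporter, damage manifests as localized regions of elevated fluorescence
("lesions") along the notochord. The quantification task is to turn a
single-channel stereomicroscope image of one fish into (i) a continuous
per-fish **severity** score and (ii) a discrete **lesion count**, and then
to compare experimental groups (control, lesioned, immune-depleted
rescues) with rank-based statistics.

The pipeline has three steps:

1. **Segmentation.** Notochord pixels are detected by a manually chosen
   intensity threshold (`threshold_mask()`, inclusion is `>= threshold`).
   The largest 8-connected component is kept (`largest_component()`) so
   stray bright debris cannot enter the fit; an Otsu fallback
   (`auto_threshold()`) exists but manual thresholding is the default,
   published behaviour.
2. **Centerline and profile.** The notochord axis is modelled as a
   degree-6 polynomial `y = f(x)` fitted by unweighted ordinary least
   squares to *all* mask pixels (`fit_polynomial_centerline()`). The image
   is then sampled along the fitted curve at uniform arc-length spacing by
   bilinear interpolation (`extract_profile()`) — a profile-line sampler
   generalised from a straight segment to a polynomial path.
3. **Scoring.** Severity is the arithmetic mean of the profile
   (`severity_score()`). Lesions are profile peaks with higher intensity
   and broader area under the peak (`detect_peaks()`); a fish is
   *affected* with more than 3 lesions and *severe* with more than 5
   (`classify_fish()`). Groups are compared with the Kruskal–Wallis
   omnibus test, Dunn's pairwise post hoc and Bonferroni adjustment
   (`kruskal_wallis()`, `dunn_posthoc()`), or Mann–Whitney for two groups.

Coordinates are 0-based `(x, y)` with `x` the column, origin top-left,
pixel centers at integer positions; this convention is used everywhere.

## The peak criterion, made operational

The source procedure defines severity numerically (the profile mean) but
describes lesions only qualitatively. `detect_peaks()` makes that
operational with all constants exposed:

* baseline `b` = profile median; dispersion `s = 1.4826 * MAD` (robust to
  the lesions themselves);
* candidates = local maxima at least `b + k*s`, default `k = 3`;
* candidates closer than `min_separation` (default 10 arc-length px) merge,
  keeping the higher;
* each peak's **area** is the trapezoid integral above `b` between its
  flanking minima, taken as the nearest return to baseline on each side
  (searching no further than the neighbouring peak, with the window
  minimum as fallback). Bounding the peak at the nearest baseline crossing
  rather than at the lowest point of the whole inter-peak segment matters:
  under noise the latter would sweep up positive noise over hundreds of
  pixels and make every candidate's area grow with profile length,
  destroying the area criterion's discriminative power;
* calls with area below `min_area` are dropped.

The height gate alone does not control false positives on long profiles:
for near-independent Gaussian profile noise the expected number of local
maxima exceeding `b + 3s` is about 1.3 per 1000 samples, so some
lesion-free fish would always show spurious calls. The **area floor** is
what embodies "broader area under the peak": a noise spike a few samples
wide has area of order `s` times a few pixels, while a genuine lesion of
amplitude `A` and width `sigma` has area about `A * sigma * sqrt(2*pi)` —
two orders of magnitude larger under the default study conditions. The
pipeline default `min_area = 15000` grey·px sits between those regimes
(noise spikes ~ 10^3, lesions ~ 10^5 on the default 16-bit scale).
`min_area` is on the grey-value scale of the input images and must be
rescaled for data on other scales; `detect_peaks()` itself defaults to
`min_area = 0` so the bare operation imposes no floor.

## Synthetic study conditions

No raw images are distributed, so the generator (`tube_model()`,
`lesion_spec()`, `ground_truth()`, `generate_cohort()`) emulates the
statistical structure the analysis assumes, with full ground truth. The
defaults, chosen once as a realistic rendering of 16-bit stereomicroscope
frames, are:

| parameter | default | meaning |
|---|---|---|
| frame | 512 × 120 px | one fish, notochord roughly horizontal |
| background / tube intensity | 500 / 10000 | bright tube on dim background |
| tube radius | 10 px | hard-edged band, optional Gaussian edge blur (sigma 1 px in cohorts) |
| pixel noise sigma | 400 | additive Gaussian, then integer quantisation and clipping |
| lesion width sigma | 6 px | Gaussian bump added to in-tube pixels only |
| lesion amplitude | uniform 4000–8000 | 10–20 noise sigmas |
| lesion spacing / margin | ≥ 40 px / 30 px | separable peaks away from the ends |
| lesion counts | control 0; lesioned Poisson(5); strong rescue Poisson(1); partial rescue Poisson(3) | Poisson(5) gives ~73% of fish with more than 3 lesions, matching the reported ~70% affected fraction |

Per-fish RNG streams are derived by hashing (cohort seed, fish index), so
cohorts are extensible without reshuffling, and identical specifications
render bit-identical images. Centerlines are gentle random cubics kept
inside the frame.

What the generator does **not** emulate: autofluorescence texture,
pigment melanocytes, depth-dependent blur, multi-fish frames, or any 3D
structure. Passing recovery tests therefore demonstrates correctness of
the measurement chain on images satisfying the model's assumptions, not
robustness to every artefact of real microscopy.

## Numerical choices

* **Conditioning.** The polynomial fit is solved on x rescaled to
  [-1, 1]; raw powers of pixel x up to 6 would lose ~16 digits at a
  512-px domain. Coefficients are reported in pixel units; prediction
  uses the rescaled form.
* **Arc-length sampling.** Dense x grid (50 subdivisions per pixel),
  cumulative chord length, linear inversion; tangents from the analytic
  derivative. Against adaptive quadrature of the arc-length integral the
  total length agrees to < 1e-3 px.
* **Interpolation.** Bilinear; exact on affine intensity fields. Samples
  outside the image (any subsample, when `linewidth > 1`) are dropped,
  not clamped, and the dropped count is reported. `linewidth` must be
  odd; default 1 (a single sample on the curve), matching straight
  profile-line defaults.
* **Orientation.** `y` is fitted as a function of `x`; if a mask's
  bounding box is taller than wide the pipeline transposes the image
  first and says so.
* **Otsu fallback.** Between-class variance is scanned over the observed
  integer histogram; the returned threshold is the midpoint between the
  adjacent class-boundary levels, which yields the same mask as any
  threshold in that gap.
* **Ties and degenerate inputs.** Component-size ties break by smallest
  minimum x then minimum y. All-identical samples give H = 0, p = 1.
  Mann–Whitney p-values are exact (full enumeration) only for untied
  samples with `n_a * n_b <= 400`; otherwise normal approximation with
  tie-corrected variance and continuity correction. Dunn's variance uses
  the pooled tie correction with the `12(N-1)` denominator (the 1964
  form; other formulations exist). A parametric one-way ANOVA, where
  wanted, is `stats::aov`/`oneway.test` on the same long-format data and
  is deliberately not re-wrapped here.
* **Spine rubric.** Counts are integers, which makes the printed
  intervals exhaustive: 0 → 0, 1–3 → 1, 4 → 2, ≥5 → 3. Fusions and
  clefts are scored independently by default, with the fish score as
  their maximum; a `combined` mode applies the rubric to the summed
  count. Neither mode is privileged as the historical ground truth —
  the source is ambiguous on this point.
* **TMD calibration.** The affine map through the 0.25 and 0.75 g/cm³ HA
  phantoms is exact at the phantoms; values outside the phantom range
  (including negative densities) are extrapolated as-is and flagged,
  never clamped — visible data problems beat silent correction.
* **Stain channel means.** Computed on raw channel values; display-time
  lookup-table inversions are treated as display transforms and ignored.

## Known limitations

* **Centerline accuracy is slope-dependent.** The per-column centroid of
  a hard-edged rasterised band deviates from the true centerline by a
  sawtooth `0.5 - frac(f(x))`, bounded by 0.5 px. Where the centerline
  has moderate slope the sawtooth cycles quickly and the degree-6 OLS fit
  averages it away (errors ~0.05–0.1 px). Where the centerline is locally
  flat, the sawtooth varies slowly enough for the polynomial to absorb it
  coherently, and end leverage can push the fit error to ~1 px. This is a
  property of the estimator (unweighted OLS over all mask pixels), not of
  its implementation; a skeleton- or edge-based centroid model would
  behave differently but is out of scope.
* **Severity has O(1/N) endpoint sensitivity.** The severity statistic is
  a plain mean over N profile samples; changing the sampling step changes
  which endpoints are included and perturbs the mean by about
  `f(end)/N`. Only for fields that are affine along the curve is the mean
  step-invariant. Comparisons should therefore use one step setting
  across a study (the config is stamped into every output for this
  reason).
* **Peak-calling constants are scale-bound.** `k`, `min_separation` and
  especially `min_area` are tuned to the generator's 16-bit scale and
  must be re-chosen for data with other dynamic ranges.
* The severity mean conflates lesion brightness with lesion extent; two
  phenotypes with equal mean but different peak structure are
  distinguished only by the lesion count.

## Problem sizes used by the test suite

Recovery tests run on 512 × 120 frames: 50-image cohorts for lesion-count
and classification recovery, 20 random geometries for centerline
recovery, 10,000 replicates of three groups of 10 for the Kruskal–Wallis
null-level check, and a 2 × 3-fish cohort for byte-level reproducibility
of a full simulate → quantify → report run.
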