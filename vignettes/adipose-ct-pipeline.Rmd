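---
title: "Methods: automated CT adipose quantification and its survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated CT adipose quantification and its survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoct)
```

## What the package computes

Body composition on abdominal CT is usually sampled at the mid-axial plane of
the third lumbar vertebra (L3), where a single slice is a good proxy for total
abdominal adipose volume. From one calibrated L3 slice, `adipoct` quantifies

* **SAT**, the subcutaneous adipose tissue area: adipose-classified pixels
  between the skin surface and the outer surface of the abdominal-wall
  musculature;
* **VAT**, the visceral adipose tissue area: adipose-classified pixels inside
  the abdominal wall; and
* **VSR = VAT / SAT**, the visceral-to-subcutaneous area ratio.

Downstream, the package relates these biomarkers to all-cause mortality with
percentile- and quartile-binned Cox proportional-hazards models, extreme-
quartile hazard-ratio ratios, Wald heterogeneity tests, and Kaplan–Meier
curves. Because no patient images or outcomes ship with the package, both
halves are exercised against synthetic data whose truth is known by
construction: parametric CT phantoms with analytic compartment areas, and
simulated cohorts with a known proportional-hazards mechanism.

## The segmentation procedure

Segmentation runs in five stages on an HU-normalized slice
(`segment_slice()`); every tunable lives in `segment_config()`.

1. **Body mask** (`make_body_mask()`). Air is region-grown from all border
   pixels across 8-connected neighbours below `air_hu` (default −400 HU,
   roughly halfway between air and fat, insensitive to noise of 10–20 HU).
   Among the non-air objects, only the largest connected component is kept —
   this is what removes the CT table and cables, which are separated from the
   body by air. Internal holes (bowel gas) are filled so the mask is simply
   connected. An empty mask, or one touching all four borders, raises a
   segmentation failure that maps onto the cohort-level *tool failure*
   exclusion.
2. **Denoising** (`denoise()`). Perona–Malik anisotropic diffusion with the
   exponential conductance `exp(-(grad/kappa)^2)`, `kappa` = 50 HU, time step
   `dt` = 0.125 (stable for the 4-neighbour stencil up to 0.25), 5
   iterations. `kappa` is set well below the ≈140 HU fat/muscle contrast, so
   that interface conducts almost nothing and survives, while homogeneous
   regions diffuse like a heat equation; at the defaults the noise standard
   deviation inside a uniform fat region drops by well over 30% and the
   image mean moves by < 0.5 HU (the symmetric flux form is conservative up
   to boundary effects).
3. **Adipose labeling** (`label_adipose()`). A pixel is adipose iff its
   denoised HU lies in the **closed** interval [−274, −49] and it is inside
   the body mask. The band is applied after diffusion, in the order the
   stages are listed. Closedness at both ends is asserted by tests at the
   exact boundary values.
4. **Contours** (`fit_contours()`). The external contour is the body-mask
   boundary (the skin). The internal contour is found morphologically: the
   adipose pixels connected to the skin band are the subcutaneous-ring
   candidate; a seed obtained by eroding the body mask past that ring
   (`erosion_radius_mm` = 30 mm, shrinking if the seed vanishes and deepening
   while the seed boundary still averages adipose HU) is then grown by unit
   geodesic dilations constrained to non-ring tissue until the mean front
   displacement per iteration falls below `tol` = 0.1 px (cap `max_iter` =
   200). The filled result's boundary locks onto the **outer** surface of the
   abdominal-wall musculature — the target we chose where "around the
   musculature" is ambiguous. Erosion and dilation by a true Euclidean radius
   use the distance transform, so a disk phantom yields contours within one
   pixel of the analytic radii. Collapse below 5% of the body area is a
   segmentation failure.
5. **Quantification** (`quantify()`). SAT/VAT pixel counts times the pixel
   area give areas in mm² (and cm² = mm²/100 exactly). When SAT is zero the
   VSR is reported as undefined (`NA`), never infinity.

A color-coded QA overlay (`render_qa()`) writes the windowed slice with VAT
in gold, SAT in blue, both contours, and an annotation strip with the three
numbers — the per-scan artifact a reader inspects to accept or reject a
segmentation.

### Preprocessing

`normalize_orientation()` permutes/flips volumes into Left-Anterior-Superior
axis order from an explicit three-letter tag (derived from DICOM/NIfTI
metadata); a missing tag is an error, never a silent default.
`resample_slices()` linearly interpolates a stack onto a contiguous grid
(default 3 mm); the default 2-D pipeline skips it, since one L3 slice is the
unit of analysis. `normalize_hu()` removes a constant vendor CT-number
offset by anchoring on border-connected air: the paper trail for how vendors'
offsets are measured is thin, and air anchoring (mean of the border-connected
low-HU region pulled to −1000) is the standard, testable choice. A provisional
histogram shift lets the anchor catch even pathological offsets (±1000 HU),
and an image without air/tissue contrast is rejected.

## The phantom generator

`generate_phantom()` paints, in order: air background, a CT table slab
(separated from the body by a 5 mm air gap, so table removal is testable by
connectivity), body soft tissue, an elliptical SAT ring whose thickness may
vary smoothly with angle, an abdominal-wall muscle ring, and a visceral
cavity with soft-tissue organ blobs, a vertebral-body surrogate, and fat
blobs placed by rejection sampling from a deterministic candidate stream —
painting stops when the target cavity fat fraction is reached, which makes
the VAT area monotone in `visceral_fat_fraction` at a fixed seed. Gaussian
HU noise (default sd 10 HU, a typical soft-tissue-kernel value) and the
vendor offset are added last. Ground truth is the noise-free label image;
areas are exact pixel counts of the painted masks, and for pure-ellipse
specs they agree with closed-form ring areas to within boundary
discretization (< 2%, < 0.01% at 1 mm pixels).

What the phantom does *not* emulate: realistic organ anatomy, an incomplete
or fenestrated abdominal wall (real muscle has gaps where SAT and VAT touch),
beam hardening, metal artifacts, and contrast-phase HU shifts. Passing the
phantom suite therefore demonstrates the pipeline's correctness on its own
geometric contract — not clinical-grade accuracy on patients, which the
original tool established through validation on real cohorts.

## The cohort simulator

`simulate_cohort()` draws each subject's (sex, age-group) stratum from
weights mirroring a large adult CT cohort (52% female; age bands 18–39,
40–59, 60–79, 80+), then SAT and VAT from log-correlated lognormals fitted
per stratum to published-style median/IQR targets, with VSR always derived
as the ratio. A two-parameter lognormal cannot match a median *and* both IQR
endpoints of these skewed cells, so we match the median exactly
(`meanlog = log(median)`) and the IQR ratio exactly
(`sdlog = log(q3/q1)/1.349`); the individual quartile endpoints are then
approximated within about 10%. A shifted three-parameter lognormal would fit
all three quantiles but puts appreciable mass below zero for some cells, so
it was rejected.

Mortality follows a proportional-hazards mechanism: an exponential baseline
rate per age group (defaults chosen so roughly a fifth of the cohort dies
within a two-decade horizon, rising steeply with age) multiplied by
`exp(log_hr)` of the subject's within-stratum quartile of the driving
biomarker (default VSR). Censoring is a uniform last-contact time on the
administrative horizon (default 21 years). Quartile effects are step
functions because the downstream analysis is quartile-binned.

For the parameter-recovery study we simulate the strongest published-style
cell (women 18–39) with a *graded* effect vector (1, 1.5, 2.2, 3.3): the
recovery target is the Q4:Q1 ratio 3.3, and a monotone dose–response — the
shape actually observed for VSR — keeps the extreme-bin identification
unambiguous, so the coverage check measures estimation, not bin selection.
At n = 20,000 per replicate the 95% Wald CI of `extreme_quartile_ratio()`
covers 3.3 in ≈95 of 100 replicates.

## The statistical pipeline

* **Exclusions** (`apply_exclusions()`): earliest CT per patient, then in
  fixed order tool failure → biomarker outliers (defaults: areas in
  (0, 1500] cm², VSR in (0, 10]; the source bounds are unpublished, so these
  are config-exposed) → age < 18 → missing data, each record counted once.
* **Binning** (`assign_bins()`): type-7 (inclusive linear interpolation)
  percentile cut points within each stratum; intervals left-closed/right-open
  except the last. The twelve-bin scheme uses edges
  {0,5,10,20,…,90,95,100} — finer in the tails where hazard curves bend.
* **Cox fits** (`cox_fit()`): partial likelihood with Breslow tie handling
  (Efron optional), bins as indicators against a reference — Q1 for
  quartiles, the 40–50th-percentile bin for the twelve-bin scheme, a
  mid-distribution reference that keeps both tails interpretable. CIs are
  log-scale Wald, `exp(coef ± 1.96 se)`. Published tables in this area
  sometimes print HR-scale symmetric CIs; we deliberately implement the
  standard convention and do not reverse-engineer the other. Bins with no
  events are flagged non-estimable and the fit continues.
* **Extreme-quartile ratio** (`extreme_quartile_ratio()`): ratio of the
  highest- to lowest-risk quartile HRs, `exp(coef_high − coef_low)`, with a
  delta-method CI from the full coefficient covariance (reference terms
  contribute zero variance). Tests confirm the delta-method se equals the
  direct se after refitting with the lowest-risk bin as reference.
* **Heterogeneity** (`heterogeneity_test()`): Wald chi-squared that all
  non-reference coefficients vanish, df = estimable bins; the captions this
  mirrors are ambiguous about the exact chi-squared construction, so the
  within-fit Wald test is implemented and labeled as such. Under null
  simulation its size is ≈5%.
* **Kaplan–Meier** (`km_estimate()`): product-limit estimates per group with
  the events-first convention at ties. Note one hand-example subtlety: with
  events at t = 1, 2 and a censoring at 1.5 among three subjects, the curve
  drops to **zero** at t = 2 — the last subject at risk dies — not to 1/3.
* **Report bundle** (`run_study()`): per-stratum summary, twelve-bin HR
  curves per sex, quartile HRs and extreme-quartile ratios per
  sex × age-group, and VSR Kaplan–Meier panels, as tidy CSVs and PNG
  figures, plus a JSON run log; re-running on the same input reproduces the
  outputs byte-for-byte.

The Cox and Kaplan–Meier engines are the reference implementations in the
`survival` package, wrapped behind typed interfaces; their correctness is
cross-checked in the test suite against an independently hand-written
Breslow partial-likelihood brute-force maximizer and hand-computed
product-limit curves.

## Problem sizes and numerical choices

The shipped checks run at sizes a laptop handles in about a minute:
20 randomized phantoms (noise sd 10 HU) for the ≤5% median-area-error
property; 40 enumerated ≤6-subject datasets for the 1e−4 brute-force Cox
agreement; 100 replicates of n = 20,000 for CI coverage of the true ratio
3.3; 1,000 null replicates of n = 600 for the 5% ± 2% size check; and a
200-phantom end-to-end demo (`end_to_end_demo()`) linking measured VSR
quartiles to simulated survival, with ≥90% true-vs-measured quartile
concordance required. Larger sizes change none of the qualitative
conclusions.

Degenerate inputs have defined behaviour throughout: all-air slices and
collapsed contours are tool failures; zero SAT flags the VSR undefined;
all-tied biomarker values refuse to bin; bins without events are flagged
rather than silently dropped; single-slice volumes skip resampling with a
warning.

## Known limitations

The pipeline is 2-D and single-slice by design. The internal contour assumes
a closed abdominal wall; on anatomies with large wall defects (hernias,
post-surgical) subcutaneous and visceral fat become connected and the
SAT/VAT split will degrade — on real data this is exactly what the QA image
is for. No contrast-phase correction is applied. The DICOM layer is a
minimal single-frame, explicit-VR-little-endian implementation sufficient
for round-tripping calibrated slices, not a general DICOM stack.
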