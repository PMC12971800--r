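# adipoct

Fully automated quantification of abdominal adipose tissue on a single
axial CT slice at the L3 vertebral level, and the survival analysis that
turns those measurements into mortality biomarkers.

CT is the reference standard for separating the two abdominal fat
compartments that behave very differently in disease: **visceral adipose
tissue (VAT)**, the metabolically active fat inside the abdominal cavity,
and **subcutaneous adipose tissue (SAT)**, the fat between skin and
abdominal-wall musculature. From one calibrated L3 slice, `adipoct`
computes the cross-sectional areas

SAT (cm²), VAT (cm²), and VSR = VAT / SAT,

via the classical five-step pipeline: (1) a region-growing body mask that
discards the CT table, (2) Perona–Malik anisotropic diffusion denoising,
(3) adipose labeling on the closed Hounsfield-unit band **[−274, −49] HU**,
(4) active-contour delineation of the external (skin) and internal
(abdominal wall) body contours, and (5) area totalling, with a color-coded
QA image (VAT gold, SAT blue). Upstream, it normalizes orientation, slice
geometry, and vendor HU offsets; downstream, it runs the epidemiological
analysis: exclusion cascade, percentile/quartile binning, Cox
proportional-hazards fits per bin with Breslow ties, extreme-quartile
hazard-ratio ratios with delta-method CIs, Wald heterogeneity tests, and
Kaplan–Meier curves.

Because patient data cannot ship with the package, it includes two
first-class synthetic-data generators: parametric abdominal CT phantoms
with analytic ground-truth areas (`generate_phantom()`), and survival
cohorts with published-style biomarker distributions and a known
proportional-hazards mechanism (`simulate_cohort()`). Every stage is
tested against these known truths.

Audience: researchers in CT body composition and opportunistic screening
who need a transparent, end-to-end testable reference implementation of
L3 adipose quantification plus its standard survival analysis.

## Worked example

Segment a phantom slice whose true areas are known by construction:

```r
library(adipoct)

ph  <- generate_phantom(phantom_spec(seed = 42))   # slice + ground truth
res <- segment_slice(ph$slice)
res$measures
#> SAT area: 172.6 cm^2
#> VAT area: 63.2 cm^2
#> VSR: 0.37
round(ph$truth$vsr_true, 2)
#> [1] 0.37
```

The measured SAT/VAT areas equal the painted truth (172.6 and 63.2 cm²);
on noisy phantoms the median area error stays below 5%. The two published
worked examples reproduce directly from their printed areas: VAT 198.6 /
SAT 187.3 cm² gives VSR 1.06, and VAT 23.4 / SAT 71.5 cm² gives VSR 0.33.

Simulate a cohort of 20,000 young women with a known graded VSR effect
(top-vs-bottom quartile hazard ratio 3.3) and recover it:

```r
tg <- default_biomarker_targets()[5, ]             # women 18-39
co <- simulate_cohort(sim_params(n = 20000, seed = 7, targets = tg,
        log_hr_per_quartile = c(0, log(1.5), log(2.2), log(3.3)),
        baseline_hazard = c("18-39" = 0.012)))
bins <- assign_bins(co$vsr, bin_scheme("quartile"))
fit  <- cox_fit(co$time_years, co$event, bins)
round(fit$hr, 2)
#> bin2 bin3 bin4
#> 1.40 2.03 3.21
extreme_quartile_ratio(fit)[c("ratio", "ci_low", "ci_high")]
#> $ratio   [1] 3.21   $ci_low [1] 2.92   $ci_high [1] 3.52
heterogeneity_test(fit)$p_value
#> [1] 3.02e-166
```

The quartile hazard ratios (1, 1.40, 2.03, 3.21) recover the generating
dose–response (1, 1.5, 2.2, 3.3) within sampling error, the extreme-quartile
ratio's 95% CI covers the truth, and the heterogeneity test rejects the
flat-hazard null, as it should with 4,278 events.

`run_study()` produces the full report bundle (per-stratum summary,
12-percentile-bin HR curves, quartile HRs, extreme-quartile ratios, KM
panels) from any cohort CSV, and `end_to_end_demo()` chains everything:
phantoms → segmentation → simulated survival from true VSR quartiles →
analysis on measured VSR.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/adipoct.R phantom  --out slice.nii --seed 3
Rscript inst/cli/adipoct.R segment  --in slice.nii --out measures.json --qa qa.png
Rscript inst/cli/adipoct.R simulate --n 10000 --seed 7 --out cohort.csv
Rscript inst/cli/adipoct.R analyze  --cohort cohort.csv --outdir results/
Rscript inst/cli/adipoct.R demo     --seed 1 --outdir demo/
```

## Package layout

| Path | Contents |
|---|---|
| `R/phantom.R`, `R/dicom.R` | phantom generator, NIfTI/DICOM round trip |
| `R/preprocess.R` | orientation, slice resampling, HU-offset removal |
| `R/segmentation.R`, `R/render_qa.R` | the five-step pipeline and QA image |
| `R/cohort_sim.R` | survival-cohort simulator |
| `R/survival_analysis.R`, `R/run_study.R` | exclusions, binning, Cox/KM, report bundle |
| `R/pipeline.R` | batch segmentation, end-to-end demo |
| `vignettes/adipose-ct-pipeline.Rmd` | methods, assumptions, tunables, limitations |
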