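# cmragree

Repeatability and reproducibility analysis of left-ventricular (LV) metrics
derived from short-axis cardiac MR segmentations.

When several readers trace the LV endocardium in several software packages,
the same heart yields different end-diastolic/end-systolic volumes (EDV,
ESV), ejection fractions (LVEF) and circumferential strains, because the
packages represent the border differently (marker points joined by a spline
versus binary masks summarised by a convex hull) and because readers differ.
`cmragree` implements the full measurement chain and the agreement statistics
used to quantify those effects, together with a synthetic deformable LV
phantom with analytic ground truth for validating the chain end to end.

## What it computes

* **Contour geometry** — arc length and enclosed area of the closed periodic
  cubic spline through marker points (`spline_perimeter()`, `spline_area()`),
  and perimeter/area of the convex hull of a binary mask's foreground pixel
  centres (`hull_perimeter()`, `hull_area()`); cm and cm² throughout.
* **Clinical metrics** — composite midpoint volumes
  `V(f) = Σ_s A(s,f)·Δz` (mL), ED/ES as the volume extrema,
  `LVEF = 100·(EDV−ESV)/EDV`, per-slice circumferential strain
  `ε(s,n) = (L_{s,n} − L_{s,ED}) / L_{s,ED}`, and the peak apical, mid,
  basal and global strains ACS/MCS/BCS/GCS as extrema of the regional mean
  strain curves (`clinical_metrics()`).
* **Agreement statistics** — group summaries (mean, SD, SD as % of mean,
  t-based 95 % CI), paired t-test comparisons within and between software
  with a Bonferroni-corrected threshold (`alpha/m`, reported 0.007 for
  `m = 7` metrics), and Bland–Altman bias with 95 % limits of agreement on
  contour lengths, including the convention that a single automated run is
  duplicated across both repetitions (`build_table1()`, `build_table2()`,
  `bland_altman_study()`).
* **Synthetic phantom** — an ellipsoid-cap LV (9 slices × 16 frames by
  default) with region-specific peak strains, smooth angular reader noise and
  additive per-software contour-length biases, plus analytic truth for every
  radius, perimeter, area, volume and strain (`phantom_config()`,
  `generate_study()`).

Contours are exchanged as JSON, mask stacks as NIfTI, tables as CSV.

## Worked example

```r
library(cmragree)

cfg <- phantom_config(seed = 1215)          # 7 readers x {OsiriX, ScanIP} x 2
study <- generate_study(cfg)                # 28 manual + 1 automated session
meas <- measure_study(study)                # spline perimeters/areas
met <- study_metrics(meas)                  # 29 rows of ACS..LVEF

bland_altman_study(meas)[c("comparison", "repetition", "bias")]
```

Running the packaged workflow (`analysis/01_simulate.R` …
`analysis/04_agreement.R`) with that seed prints, among other things:

```
ScanIP vs OsiriX   bias -1.89 cm, LoA [-1.96, -1.81]
OsiriX vs CVI42    bias +0.67 cm, LoA [0.61, 0.73]
ScanIP vs CVI42    bias -1.22 cm, LoA [-1.29, -1.14]
```

i.e. the injected contour-length offsets (−1.9 cm and −0.6 cm) are recovered
as Bland–Altman biases, with the small systematic excess explained in the
methods vignette (smooth reader noise inflates shorter contours slightly
more). The paired-comparison table flags every inter-software volume
comparison at the corrected threshold while intra-software comparisons stay
null, and a zero-noise phantom session recovers the configured regional
strains (−12/−20/−30 %) and analytic LVEF (40 %) to well within one
percentage point.

The numbered scripts under `analysis/` form the full study pipeline —
simulate, measure, metrics, agreement — each a thin driver over the package
functions, writing its outputs (session JSON, NIfTI masks, measurement /
metric / table CSVs, figures) under `results/`.

## Documentation

The methods vignette (`vignettes/lv-strain-agreement.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the phantom does and does not emulate, numerical and degenerate-input
choices, and known limitations.
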