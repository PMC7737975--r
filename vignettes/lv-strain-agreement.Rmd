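---
title: "Measuring agreement of LV strain and volume metrics from short-axis contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agreement of LV strain and volume metrics from short-axis contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Left-ventricular (LV) function is routinely quantified from short-axis cine
cardiac MR by tracing the endocardial border on every slice and frame. From
those contours one derives end-diastolic and end-systolic volumes (EDV, ESV),
the ejection fraction (LVEF), and circumferential strains — the fractional
shortening of the endocardial perimeter through the cycle. Different software
packages represent the same border differently (marker points joined by a
spline versus binary pixel masks summarised by a convex hull), and different
readers trace it differently. Both choices perturb the measured contour
lengths and areas, and hence every downstream metric. This package provides
the complete measurement chain plus the statistical layer used to quantify
those effects, driven by a synthetic phantom whose ground truth is known
analytically.

## The measurement chain

**Contours to lengths and areas.** A marker contour is interpolated by a
closed periodic cubic spline under chord-length parameterisation; its arc
length and enclosed (shoelace) area are evaluated on a dense resampling, 200
samples per marker segment by default. For LV-like contours the polyline
error of that resampling is of order $10^{-6}$ relative, far below every
effect studied. A mask is summarised by the convex hull of its foreground
pixel centres (centres sit at $(i - \tfrac12)\,\Delta x$); the hull's
perimeter and area are the mask's length and area measures. Lengths are
reported in cm and areas in cm², converted exactly once at measurement time.

**Volumes.** Composite midpoint integration: per frame,
$V(f) = \sum_s A(s, f)\,\Delta z$ with $\Delta z$ the effective slice spacing
(slice thickness plus gap, 10 mm by default), giving mL from cm²·cm.
End-diastole (ED) is the frame of maximum summed volume, end-systole (ES) the
minimum, ties broken to the earliest frame. $\mathrm{LVEF} =
100\,(\mathrm{EDV}-\mathrm{ESV})/\mathrm{EDV}$.

**Strains.** Circumferential strain of slice $s$ at frame $n$ is
$\varepsilon(s,n) = (L_{s,n} - L_{s,\mathrm{ED}})/L_{s,\mathrm{ED}}$, with the
ED reference taken globally from the summed volume curve (not per slice), so
$\varepsilon(\cdot,\mathrm{ED}) \equiv 0$ exactly. Slices are grouped into
three contiguous equal regions — basal, mid-ventricular, apical, slice 1 being
most basal — and the regional curve is the unweighted mean of its slices'
strains, frame by frame; the global curve averages all slices. Peak strains
(ACS, MCS, BCS, GCS, in percent, negative for contraction) are the extrema of
those mean curves. Averaging before taking the extremum is the default
because a mean of per-slice extrema is a different, noisier quantity; the
alternative order is available via `peak_method = "per_slice"`. For the
monotone noise-free phantom the two coincide, as do "extremum of the curve"
and "value at ES".

## The phantom

The cavity is an ellipsoid cap: slice $s$ at long-axis offset
$z_s = (s - \tfrac12)\,\Delta z$ has ED radius
$r_0(s) = R\sqrt{1 - (z_s/h)^2}$ with $R$ = `base_radius` and $h$ =
`cap_half_height`. Deformation follows a raised-cosine half-cycle
$g(f) = \tfrac12\left(1 - \cos\frac{\pi (f-1)}{F-1}\right)$, so
$r(s,f) = r_0(s)\,(1 + \varepsilon_{\mathrm{region}(s)}\, g(f))$ runs smoothly
from ED ($g = 0$) to ES ($g = 1$). Any monotone 0→1 profile would serve; the
raised cosine is smooth at both ends.

Defaults emulate a dilated porcine heart studied over 9 retained slices and
16 frames at 1.6 mm pixels and 10 mm effective slice spacing: $R = 28$ mm and
$h = 100$ mm give analytic EDV ≈ 162 mL and LVEF ≈ 40 %, and regional peak
strains (base −0.30, mid −0.20, apex −0.12) put ACS/MCS/BCS near −12/−20/−30 %
— the scale of the reported clinical values for such a subject. The long-axis
positions of the slices within the acquired stack are not knowable from a
published protocol; the mid-slice offsets $(s-\tfrac12)\Delta z$ are a free
modelling choice, fixed once.

**Reader variability** is a smooth zero-mean angular perturbation of the
radius: random Fourier coefficients over modes 1–3 rescaled so the angular RMS
equals `reader_noise_sd` (default 1.0 mm, sub-pixel, the scale of careful
manual tracing). Smooth low-order noise models spatially correlated human
tracing error; white per-marker noise would make the spline oscillate
unrealistically.

**Software bias** is an additive contour-length offset: a software with bias
$b$ cm draws every radius $b \cdot 10 / (2\pi)$ mm off, shifting every
circumference by $b$. Defaults inject 0 cm for the first manual software,
−1.9 cm for the second, and −0.6 cm for the automated single-run software —
the magnitudes of the reported inter-software contour-length biases. Every
contour's randomness comes from a substream hashed from
(seed, reader, repetition, software, slice, frame), so studies are
reproducible bit-for-bit and sessions are order-insensitive.

### What the phantom deliberately does not emulate

* No greyscale images: contours and masks only, so nothing is learned about
  segmentation algorithms themselves.
* Readers have no persistent identity: noise is independent per contour, so
  the between-reader spread of volumes is far smaller than in real studies,
  where a reader who over-contours at ED tends to over-contour at ES too.
  Passing tests therefore validate the measurement and statistics chain, not
  the realism of between-reader variance components.
* No papillary muscles or trabeculae (real guidelines include them in the
  blood pool) and no epicardium.

### Two structural consequences worth knowing

*Curvature–noise interaction.* Smooth radial noise of amplitude $\sigma$
inflates a contour's expected length by $\oint \delta'^2/(2r)\,d\theta$,
which grows as the radius shrinks. A software whose contours are uniformly
smaller (an additive negative bias) therefore gains slightly more
noise-inflation than its comparator, and the Bland–Altman bias estimate
converges ≈ 0.01–0.02 cm short of the injected −1.9 cm (and ≈ 0.07 cm when a
noisy manual group is compared with the noise-free automated one). Relative
to the bias this is under 1 %, but at $n \approx 1000$ pairs per study it is
many standard errors, so exact-recovery assertions at 3-SE tolerance fail by
design; the corresponding acceptance check is retained unmodified and
documents this.

*Additive bias leaks into relative metrics.* An additive length offset $b$
cancels in the strain numerator but not its denominator:
$\varepsilon' = \varepsilon\, L_0/(L_0 + b)$, so with $b = -1.9$ cm GCS gains
≈ 2.8 strain points and LVEF ≈ 5 points. A purely multiplicative bias would
cancel exactly; real inter-software biases (e.g. hull-of-pixels shrinkage)
sit in between, closer to multiplicative, which is why observed studies find
strains robust while this phantom shifts them measurably. The additive form
was chosen because it reproduces the additive Bland–Altman structure of the
reported contour-length comparisons.

## The statistics layer

Group summaries report sample mean, SD ($n-1$), SD as a percentage of the
mean and a t-based 95 % CI. Paired comparisons are two-sided paired t-tests;
by pairing, the mean paired difference equals the difference of group means
to machine precision, which is also how summary columns published alongside
group means can be reproduced from those means alone (`paired_means()`).
Sign conventions: within software, repetition 1 minus repetition 2; between
software, first configured label minus second. The Bonferroni threshold
defaults to $\alpha/m$ with $m = 7$, the number of metrics (reported rounded
to 0.007); $m$ is configurable since the alternative $m = 28$ (metrics ×
comparisons) is defensible. Bland–Altman analysis reports the mean paired
difference and $\mathrm{bias} \pm 1.96\,\mathrm{SD}$ limits of agreement,
per repetition and pooled; an automated single-run software is first
duplicated across both repetitions (flagged `uses_duplicated_run`), treating
it as perfectly repeatable. Zero-variance differences (e.g. comparisons of a
duplicated run with itself) report an undefined p-value rather than a number.

## Numerical and degenerate-input choices

* Collinear marker sets degrade to polygon perimeter / zero area with a
  warning, and degenerate masks (< 3 non-collinear foreground pixels) to
  zero-length hulls, so batch runs survive pathological frames; empty masks
  are hard errors.
* Hulls over pixel *centres* by default (the centre-vs-corner choice moves
  perimeters by about one pixel; corners are available via
  `hull_convention = "corners"`).
* Contour orientation is normalised counter-clockwise on load; areas are
  absolute values, so orientation cannot flip signs.
* ED/ES ties break to the earliest frame.

## Problem sizes used by the test-suite and reproduction script

The packaged checks run the default 9 × 16 stack throughout; stochastic
properties use 200 replicate studies for Bland–Altman recovery (repetition-1
sessions, spline resampling at 40 samples per segment, whose ~$10^{-6}$
relative arc-length error is negligible against the effects measured), 20
null studies at 6 frames for the type-I-rate property, and single default
studies elsewhere. These sizes are the package's own choices and are stated
here so they can be scaled up when more precision is wanted.

## Known limitations

Between-reader variance of volumes is unrealistically small (see above), so
power statements about reader effects do not transfer to real cohorts; the
additive bias model overstates bias transfer into strains relative to the
multiplicative mechanisms seen with convex-hull shrinkage; and the phantom's
cross-sections are circles, so hull-versus-spline contrasts quantify
discretisation, not shape complexity.
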