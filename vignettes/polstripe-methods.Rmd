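---
title: "Rotating-polarizer polarimetry of striped coats: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotating-polarizer polarimetry of striped coats: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polstripe)
```

## The measurement model

Photographing a scene through a linear polarizing filter at a sequence of
filter angles turns the polarization state of reflected light into a
luminance modulation. For partially linearly polarized light, the luminance
of a surface patch as a function of filter angle $\theta$ follows a
180°-period sinusoid

$$L(\theta) = b\,\bigl(1 + d \sin 2(\theta + \phi)\bigr)
           = b + a \sin 2(\theta + \phi), \qquad a = d\,b,$$

where $b$ is the mean (baseline) luminance, $d \in [0, 1]$ the degree of
linear polarization, and $\phi$ the polarization phase. The degree of
polarization is recovered from the extrema of the fitted curve,

$$d = \frac{L_{\max} - L_{\min}}{L_{\max} + L_{\min}} = \frac{a}{b},$$

a ratio that is invariant to the unknown, exposure-dependent scale factor
between sensor counts and luminance — the reason the whole pipeline can
work on uncalibrated raw-linear TIFFs, provided exposure is locked within a
series (`polarizer_series()` enforces the flag).

The standard capture protocol takes seven exposures with the filter rotated
from $-90°$ to $+90°$ in 30° steps. The two endpoint images are the same
physical filter orientation; their disagreement within a region of interest
estimates within-series repeatability (`replicate_endpoint_check()`), and
shrinks as the ROI area grows because pixel noise averages out.

### The phase convention

The filter angle convention puts the minimum-transmission axis vertical at
$\theta = \pm 90°$. We report the phase $\phi$ in *half-angle*
(polarization-angle-like) units on $[-90°, +90°)$, so that the sinusoid's
argument is $2(\theta + \phi)$: under this convention $\phi = -45°$ means
luminance peaks at $\theta = \pm 90°$, i.e. a preponderance of horizontally
polarized light, and $\phi = +45°$ means vertically polarized light. This
choice makes the canonical form unique: constraining the amplitude to
$a \ge 0$ folds a sign flip of $a$ into a $+90°$ shift of $\phi$, which
exactly covers the half-angle domain. Reporting the raw sinusoid-argument
phase instead would need a $[-180°, 180°)$ range and would put the
physically interesting horizontal/vertical axis at the edges of the range.

### Fitting

The model is linear in $(b,\ a\cos 2\phi,\ a\sin 2\phi)$, so
`fit_sinusoid()` uses closed-form harmonic regression on the basis
$\{1, \sin 2\theta, \cos 2\theta\}$: the global least-squares optimum,
exact and deterministic, with no starting values or iteration. A
property-level test verifies agreement with a multi-start Levenberg–
Marquardt fit of the nonlinear form to $10^{-8}$; the closed form is the
implementation, the iterative fit only an oracle.

Fit quality is summarized by `fit_r`, the Pearson correlation between
fitted and observed luminances. Phase-based analyses are gated: a region
enters them only when *both* stripe classes have `fit_r` strictly above
`critical_r(alpha, df)` with $\alpha = 0.05$ and $df = n - 1 = 6$ for the
seven-point protocol, giving the threshold $r > 0.707$. The rationale is
that the phase of a near-zero-amplitude sinusoid is noise; the Monte-Carlo
recovery test below quantifies exactly that.

**Calibration of the gate.** The printed $df = 6$ convention is a field
convention, not a textbook residual df (which would be $n - 3 = 4$ after
fitting three parameters). More importantly, `fit_r` is a *multiple*
correlation with two harmonic regressors, so under pure noise
$r^2 \sim \mathrm{Beta}(1, 2)$ on $n = 7$ points and a single class passes
$r > 0.707$ with probability $(1 - 0.707^2)^2 \approx 0.25$ — not 5%. The
both-classes requirement squares this to $\approx 6.3\%$, which is what
actually controls the gate's false-positive rate. The package implements
the conventional gate faithfully and tests its empirical calibration
against the closed-form Beta law; users wanting strict type-I control at
$\alpha$ can pass textbook df to `critical_r()` themselves.

## Stripe segmentation

`otsu_threshold()` maximizes the between-class variance
$\omega_0\omega_1(\mu_0 - \mu_1)^2$ over a 256-bin histogram of the ROI's
own luminance range — the classical adaptive grayscale threshold — with
ties broken toward the lower cut. Using the input's own range makes the
threshold equivariant under positive rescaling, so segmentation is
invariant to exposure scale; an exhaustive-search oracle test confirms the
maximizer on random bimodal samples. `segment_roi()` thresholds *each image
independently*, which keeps the same stripes identified as their absolute
luminances change with the polarizer; the brighter class is labelled white
and checked for consistency against the reference (0°-filter) image.
Degenerate ROIs — constant luminance, an empty class, or a white fraction
collapsing below 5% / above 95% in any image — are flagged excluded rather
than silently fitted.

ROI motion between exposures is handled by per-image integer offsets:
supplied manually (authoritative) or recovered by `track_roi()`, a
normalized cross-correlation search against the first image with a warning
when the peak sits on the search boundary.

## The acuity model

An approaching fly's compound eye is modelled as a Gaussian blur of angular
width 1° (the acceptance-function scale of large well-studied flies). The
width maps onto capture pixels as

$$\mathrm{width}_{px} = \mathrm{acuity}° \times \mathrm{px/deg} \times
  \frac{\mathrm{distance}}{\mathrm{capture\ distance}},$$

and is converted to a Gaussian $\sigma$ by the full-width-at-half-maximum
relation $\sigma = \mathrm{width}/2.3548$ by default. Whether a stated
"width" means FWHM or $\sigma$ is genuinely ambiguous; FWHM is the standard
parameterization of ommatidial acceptance functions, so it is the default,
and `width_convention = "sigma"` makes the other reading available rather
than hiding the ambiguity.

`blur_image()` convolves the *entire* frame (never a cropped ROI) after
mirror-padding by $3\sigma$, so region means near the ROI are free of
boundary artifacts; the convolution itself is EBImage's Gaussian filter.
`visibility_sweep()` then re-extracts class means on the blurred frames
using the original, unblurred-image masks, refits the sinusoid, and reports
degree of polarization per class, Michelson stripe contrast
$(L_w - L_b)/(L_w + L_b)$ averaged over filter settings, and the mask-free
pooled degree, at every distance. On noise-free striped scenes contrast
decays monotonically with distance (low-pass property) down to a numerical
floor around $10^{-4}$–$10^{-3}$ of its unblurred value, below which
mask-level asymmetries dominate and monotonicity is no longer meaningful;
the equal-phase class degrees converge to the luminance-weighted mixture
degree $(b_b d_b + b_w d_w)/(b_b + b_w)$ while the pooled degree stays
there throughout — polarization outlasts the stripes.

## The synthetic scene generator

`render_series()` is the forward model of the same sinusoid the fitter
estimates: hard-edged parallel bands (optional 1–2 px linear feathering)
of two stripe classes on a uniform background, each class with its own
$(b, d, \phi)$, plus additive Gaussian sensor noise clipped at zero
luminance. This deliberately sidesteps physically based rendering of hair
reflection: the measurement chain only ever sees the sinusoid, so
generating from it makes every stage testable by exact parameter recovery
(noise-free round trips recover $d$ to $10^{-12}$) while keeping ground
truth unambiguous.

What the generator does *not* emulate — and therefore what passing tests do
not show about field data: spatially correlated illumination (sun flecks,
shade gradients), curved body surfaces with varying reflection geometry,
hair-scale specularities, heat shimmer, and non-Gaussian sensor noise. The
noise magnitude itself is a free parameter; 2% of mean luminance is used as
a realistic raw-sensor figure in the study-scale defaults.

`simulate_cohort()` wires the generator to the full pipeline at cohort
scale: 21 animals × 7 ROIs by default, per-ROI white-stripe degree drawn
log-normally (median 0.12, log-SD 0.4, spanning roughly 0.05–0.4 as
observed on real coats), black degree fixed at 1.46× the white, shared
phase per ROI with 4° class jitter, and 10 paired background patches at
half the coat's mean degree. Those ratios are design targets of the
synthetic cohort, chosen to match the magnitudes reported from field
photographs; recovering them (median relative difference ≈ 46%, median
coat/vegetation ratio ≈ 2) demonstrates that the pipeline's estimators are
unbiased at realistic noise, not that the field values themselves are
reproduced.

## Numerical choices and problem sizes

- Histogram threshold: 256 bins regardless of bit depth; ties to the lower
  cut; threshold reported as a luminance at a bin boundary.
- Harmonic regression: QR factorization; rank < 3 (fewer than three
  distinct angles mod 180°) is an error, not a warning.
- Degree clipping: a fitted amplitude exceeding the baseline implies
  negative minimum luminance; $d$ is clipped to 1 with a warning
  (floating-point overshoot at exactly $d = 1$ is tolerated silently).
- `fit_r` of a constant series (or constant fit) is defined as 0.
- Blur boundary: mirror padding by $\lceil 3\sigma \rceil$, replicate
  padding beyond; kernel radius $3\sigma$.
- Test and acceptance problem sizes: scenes of 64–192 px, 500-replicate
  Monte-Carlo per parameter-grid point, a 21 × 7 cohort at 64 px per ROI
  scene — sizes at which every documented recovery holds and the full
  suite runs in well under a minute on one core.

## Known limitations

- Linear polarization only; circular components and full Stokes imaging are
  out of scope, as is raw camera decoding (ingest is TIFF).
- Phase statistics use linear Pearson correlation on a circular domain,
  matching field practice; pairs near the ±90° wrap depress the
  correlation relative to a circular statistic.
- At extreme blur the frozen stripe masks average heavily mixed pixels;
  class degrees are then estimates of the mixture, not of the classes —
  reported as-is, by design.
- The mixed-model ANOVA layer of cohort analysis is intentionally not
  reimplemented; the study table CSV is the hand-off point to any
  general-purpose modelling package.
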