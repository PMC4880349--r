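# polstripe

Rotating-polarizer imaging polarimetry of striped animal coats, in R.

Biting flies (tabanids, tsetse) orient visually toward hosts, and many are
*polarotactic*: attracted to horizontally polarized reflections. One
long-standing hypothesis holds that zebra-style striping defeats this cue.
Testing it requires measuring, from field photographs, how strongly and in
what plane light reflected from black and white stripes is polarized, how
that compares with the background vegetation, and what of either signal
survives the coarse (~1°) acuity of a fly's compound eye at host-finding
distances. `polstripe` implements that measurement chain as a tested,
reproducible pipeline.

## The method

A scene is photographed through a linear polarizing filter at seven angles
θ from −90° to +90° in 30° steps (endpoints replicated, exposure locked).
For each tracked body-region ROI, black and white stripes are separated by
an adaptive Otsu threshold per image, and each class's mean luminance is
fitted with the 180°-period sinusoid

    L(θ) = b (1 + d sin 2(θ + φ)) = b + a sin 2(θ + φ)

by closed-form harmonic regression. The degree of linear polarization is
`d = (Lmax − Lmin)/(Lmax + Lmin) = a/b` (exposure-scale invariant) and the
phase φ encodes the polarization plane: φ = −45° ⇔ luminance peaks at
θ = ±90° ⇔ predominantly horizontally polarized light. Phase analyses are
gated on fit quality for both classes (r > 0.71 at α = 0.05, df = 6 for
the 7-point protocol). Stripe salience is the Michelson contrast
`(Lw − Lb)/(Lw + Lb)` averaged over filter settings. A distance sweep
blurs the frames with a 1°-FWHM Gaussian scaled by observer distance and
recomputes everything, producing visibility-versus-distance curves.

Because no field photographs ship with the package, a synthetic scene
generator (`render_series()`, `simulate_cohort()`) produces polarizer
series of striped targets with known per-class (b, d, φ) ground truth;
every stage is tested by parameter recovery against it.

## Worked example

```r
library(polstripe)

cfg <- scene_config(
  black_spec = stripe_class_spec(60, 0.30, -45),   # b, d, phase
  white_spec = stripe_class_spec(180, 0.15, -45),
  background_spec = stripe_class_spec(120, 0.10, -45),
  noise_sd = 1.5, seed = 42)
series <- render_series(cfg)
series
#> Polarizer series: 7 images of 96 x 96 px, angles [-90, -60, -30, 0, 30, 60, 90] deg
#>   89.5 px/deg, captured at 50 m, exposure locked

flank <- roi("flank", 20, 20, 40, 40)
seg <- segment_roi(series, flank)
pol <- roi_polarimetry(series, seg)
pol
#> ROI polarimetry: d_black = 0.3002, d_white = 0.1498, contrast = 0.4978, gated = TRUE
pol$black
#> Sinusoid fit (n = 7): a = 18.02, b = 60.01, phase = -44.99 deg, d = 0.3002, r = 1.000
```

The generator's black stripes were built with d = 0.30 and phase −45°
(horizontal polarization); the fit recovers d = 0.3002 and −44.99° from
the noisy rendered series, passes the r > 0.71 gate, and the black/white
Michelson contrast is 0.498. The distance sweep shows the central
phenomenon — stripe contrast collapses with distance while the pooled
polarization signal persists:

```r
cv <- visibility_sweep(series, flank, seg,
  acuity_config(distance_grid_m = c(1, 5, 10, 20, 50),
                pixels_per_degree = 20, capture_distance_m = 10))
print(cv, digits = 3)
#>   distance_m sigma_px d_black d_white d_pooled  contrast
#> 1          1    0.849   0.271   0.154    0.187  4.24e-01
#> 2          5    4.247   0.200   0.176    0.187  1.02e-01
#> 3         10    8.493   0.183   0.182    0.183  2.14e-03
#> 4         20   16.986   0.170   0.170    0.170 -7.40e-05
#> 5         50   42.466   0.150   0.150    0.150  6.19e-07
```

By 10 m the stripes are gone (contrast ~0.002) and the two class degrees
have merged, but the region still carries a polarization degree near the
luminance-weighted mixture value 0.1875 — a signal a polarotactic insect
could use after the pattern itself is invisible.

Field-style series on disk are handled by `load_series()` /
`write_series()` (16-bit TIFF + YAML sidecar), cohort-level comparisons by
`stripe_d_comparison()`, `phase_correlation()`, `cohort_summary()` and
`background_comparison()`, and a YAML-driven command-line workflow by
`inst/cli/polstripe.R` (`simulate | analyze | sweep`).

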