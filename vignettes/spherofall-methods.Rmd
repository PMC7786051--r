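---
title: "Measuring spheroid weight, diameter and mass density from free-fall sedimentation"
author: "spherofall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spheroid weight, diameter and mass density from free-fall sedimentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherofall)
```

## The measurement principle

A tumor spheroid released into a vertical channel filled with quiescent
buffer reaches its terminal velocity within milliseconds and then falls at
constant speed. For a rigid sphere at low Reynolds number, drag is linear
in velocity (Stokes regime), so the force balance between gravity,
buoyancy and drag gives

$$v = \frac{2 r^2 g\,(\rho_s - \rho_f)}{9 \mu},$$

with $r$ the spheroid radius, $\rho_s$ its mass density, $\rho_f$ and
$\mu$ the density and dynamic viscosity of the fluid, and $g$ the
gravitational acceleration. Observing $v$ (from bright-field video) and
$r$ (from the segmented silhouette) therefore determines the density by
algebraic inversion,

$$\rho_s = \rho_f + \frac{9 \mu v}{2 r^2 g},$$

and with it the volume $V = \tfrac{4}{3}\pi r^3$ and the total mass
("weight") $W = \rho_s V$. The package reports the triplet the assay is
built around: diameter in µm, weight in ng and mass density in fg/µm³
(numerically 1 fg/µm³ = 1 kg/m³). Mass density is the most robust of the
three: any perturbation that scales diameter and weight concordantly —
fixation being the practically important example — cancels in the ratio,
which the test suite exercises as an invariance property.

Working assumptions: a rigid, impermeable, spherical particle in an
unbounded quiescent Newtonian fluid. Spheroids of 60–200 µm diameter
settling at up to ~1 mm/s in watery buffer sit at $Re \lesssim 0.1$, at
the edge of the creeping-flow regime; `reynolds_number()` computes the
actual value and warns past a configurable threshold (default 0.1)
without altering results. An optional multiplicative wall-correction
factor (default 1, i.e. none) is exposed for confined channels; no
non-spherical drag model and no pre-terminal transient is modelled.

## From frames to a velocity

Each repetition (one recorded free fall of the same spheroid) is
processed per frame: the dark object is segmented from the bright
background with an Otsu histogram-split threshold, holes are filled,
connected components below 500 px² (configurable) are discarded, and the
*circular reference* is fitted as the **minimal enclosing circle** of the
component — computed exactly with Welzl's algorithm on the convex hull of
the boundary pixels. The enclosing circle was chosen over an
equivalent-area fit because the radius rule downstream consumes *maximum*
radii, and because it degrades gracefully for slightly irregular
spheroids. The sub-pixel centroid is the intensity-weighted first moment
of the component. Quality flags (`ok`, `low_contrast`,
`touching_border`, `multiple_candidates`) replace the operator's visual
screening of the original workflow; only `ok` detections enter the
analysis. Frames with no detectable object are recorded as gaps and
simply skipped — ordinary least squares tolerates irregular sampling, so
no interpolation is performed.

The vertical centroid position (row index, increasing along the fall, in
µm) is regressed on time per repetition; the slope is that repetition's
terminal velocity, reported with its standard error and $r^2$. A
`discard_first` option can drop initial frames, but its default is 0: the
velocity relaxation time $\tau = m/(6\pi\mu r)$ of a 150 µm spheroid is
of order milliseconds, well below one frame interval at 30 fps.

## Aggregation: the final-radius rule

Per spheroid, at least 3 (typically 10) repetitions are aggregated:

- radius = mean over repetitions of each repetition's **maximum**
  detected radius;
- terminal velocity = mean of the per-repetition slopes;
- density and weight are then computed **once** from the aggregated
  $(\bar v, \bar r)$ pair, not averaged over per-repetition densities,
  mirroring how the physical method extrapolates its values.

The max-radius rule has a quantifiable statistical cost that users should
know about: under per-frame radius jitter of standard deviation
$\sigma_r$, the maximum of $n$ frames is biased upward by roughly
$\sigma_r \Phi^{-1}(n/(n+1)) \approx 2\sigma_r$ for $n = 30$. With the
simulator's default jitter of 0.1 px (0.2 µm at 2 µm/px) this inflates a
75 µm radius by ~0.5 % and hence weight by ~1.6 %, while density — which
depends on $v/r^2$ with both biases partially cancelling — moves by
under 0.1 %. This bias is a property of the measurement rule itself, it
is visible in the package's recovery numbers, and it cancels in
between-cohort percent changes (both arms share it multiplicatively).

## The QC chain and cohort comparison

Cohorts are screened per condition over the four reported metrics —
terminal velocity, mass density, diameter, weight:

1. Shapiro–Wilk normality test per metric at $\alpha = 0.05$ (the
   conventional level; the assay's description fixes none).
2. For metrics that fail normality (or all metrics, with
   `force_screen = TRUE` — the conditional reading is the default since
   screening is described as triggered by non-normal distributions),
   Tukey box-plot fences at $Q_1 - 1.5\,\mathrm{IQR}$ and
   $Q_3 + 1.5\,\mathrm{IQR}$, with quartiles by linear interpolation
   (type 7); values strictly outside a fence are flagged, values exactly
   on a fence are not.
3. **Any-metric removal**: one flag in any metric removes the spheroid.
   The removed set is the union, never the intersection, of per-metric
   flag sets, and every (spheroid, metric) flag is kept in a ledger.
4. Shapiro–Wilk is re-run on the survivors to confirm normality.

Constant (degenerate) metric vectors are reported as such rather than
screened. Treatment effects are quantified per metric as the signed
percent change of the treated mean relative to control, with a two-tailed
unpaired Student's *t*-test using the pooled variance (the classical
Student form, not Welch). No multiple-testing correction is applied
across metrics, matching the source workflow's reporting convention.

## The synthetic generator

Because no public raw data exist for this device class, the package
ships a generator whose defaults *are* the study conditions: cohorts of
10 spheroids × 10 repetitions; radii from a truncated normal within
30–100 µm (diameters 60–200 µm); densities normal, truncated above the
fluid density (a non-sinking spheroid never transits the channel);
DPBS-like fluid (ρ = 1005 fg/µm³, µ = 0.89 mPa·s at 25 °C); 30 frames
per repetition at 30 fps, 2 µm/px, 512×512 rasters. Stochastic terms:
centroid localization noise (default 0.5 px per coordinate), per-frame
radius jitter (default 0.1 px — the circle fit of a high-contrast disc
is much more stable than its centroid estimate), and, for rendered
frames, Gaussian optical blur (σ = 1 px) plus additive intensity noise
on an 8-bit-like scale. Ground truth always satisfies the forward model
exactly, and identical configuration + seed reproduces every byte.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: non-spherical and textured spheroids,
debris and bubbles, illumination gradients, Brownian motion (negligible
at 100 µm, but real), pump-induced residual flow (a constant-drift hook
exists), and frame-rate or magnification quirks of the actual device.
Preset cohorts (`ht29`, `sw620`, `dld1`, `hct15` and NK-treatment
variants) are deliberately loose caricatures that reproduce qualitative
orderings — e.g. the lighter, low-density, dispersed character of the
HT-29-like cohort — for pipeline testing, not estimates of the real
lines. The NK presets program weight/diameter reductions of the
magnitude the assay is meant to resolve (weight × 0.53 ≙ −47 %).

## Numerical and design choices

- **Units.** µm, s, µm/s, fg/µm³ and ng at every public boundary; all
  hydrodynamics evaluated in SI internally; $g = 9.80665$ m/s² fixed.
- **Weight is total mass** $\rho_s V$, not buoyant mass: only this
  convention is consistent with ng-scale magnitudes and with density
  normalizing weight and diameter concordantly.
- **Fluid from temperature.** When only a temperature is known, the
  buffer is treated as water-like via a Vogel-type viscosity correlation
  and Kell's density polynomial (valid 4–40 °C); explicit values always
  override.
- **Degenerate inputs.** Blank frames, constant samples, sub-minimal
  cohorts and zero pooled variances raise classed errors
  (`spherofall_invalid` for bad parameters, `spherofall_data` for
  unusable data; the CLI maps them to exit codes 2 and 3) instead of
  propagating NaNs.
- **Tie-breaks.** Among multiple above-threshold components the one
  nearest the previous detection wins, else the largest.
- **Problem sizes in the validation suite.** The shipped checks use
  cohorts of 10×10 (recovery, effect detection), 100 spheroids × 5
  repetitions (distribution invariance), 100–1000 replicates for
  calibration rates, and 100 rendered discs for detection accuracy —
  sizes chosen to keep the full suite comfortably interactive while
  leaving Monte-Carlo noise well inside the asserted bands.
- **Paired-seed invariance check.** The density-invariance property
  (radii × k, masses × k³) is verified on cohorts generated from the same
  seed, i.e. the *same* spheroids before and after scaling, so the
  Kolmogorov–Smirnov distance isolates the scaling effect rather than
  sampling noise of two independent n = 100 draws. The −47 % recovery
  check, by contrast, uses independently seeded arms under low (5 % CV)
  biological variance, the regime in which a 10-vs-10 comparison can
  resolve percent changes to a few points.

## Known limitations

The inversion inherits every Stokes assumption: porous or strongly
aspherical aggregates violate the rigid-sphere drag and bias density
toward the fluid's; wall proximity retards settling (the correction
factor is exposed but defaults to off); at Re above ~0.1 the linear drag
law progressively underestimates drag. The detection stage assumes one
object per frame on a bright background and makes no attempt at
illumination correction beyond the global threshold. The QC chain
presumes roughly normal cohorts of at least 4 spheroids per condition;
with fewer it refuses rather than guesses.
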