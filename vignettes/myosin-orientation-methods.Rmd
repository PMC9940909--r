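---
title: "Quantifying myosin-II orientation during germband extension: models and methods"
author: "gbeorient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myosin-II orientation during germband extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbeorient)
```

## The scientific problem

During *Drosophila* germband extension (GBE), anisotropic non-muscle
myosin II on cell-cell junctions drives convergent-extension flow. Two
candidate control regimes make opposite predictions about how the
*orientation* of myosin anisotropy evolves while the tissue flows:

* if myosin orientation is instructed cell-intrinsically (e.g. by
  pair-rule gene, PRG, expression differences between neighbors), the
  pattern should be carried along with the cells — it deforms by passive
  advection, like the PRG stripes themselves;
* if myosin is recruited by a *static, geometrically defined source* —
  junctions parallel to the embryo's dorsal-ventral (DV) axis recruit
  myosin preferentially — the orientation pattern stays anchored to the
  egg, deflecting only transiently where the tissue rotates.

This package implements the quantitative analyses that discriminate the
two regimes on 2D cylindrical pullback maps of the embryo surface, and a
synthetic-embryo generator that emulates the statistical structure of
the imaging data so that every stage is testable without any microscopy
download.

## Chart conventions

All fields live on a cylindrical chart (`make_chart()`): x runs along
the anterior-posterior (AP) axis (posterior to the right), y along the
DV circumference and is periodic; the ventral midline is at y = 0 and
the dorsal midline at half the circumference. The DV axis is the +y unit
vector, the chart proxy for the direction of maximal surface curvature.
Junction and stripe orientations are *nematic* angles in (-90, 90]
degrees measured counterclockwise from the DV axis; 0 means
DV-parallel. The counterclockwise sign matches the sign of the rotation
rate, so a region of positive vorticity rotates both passive lines and
the measured angles in the positive direction — the convention is used
consistently by the generator, the Radon detector, the stripe-angle
field, and the relaxation model. Wild-type defaults are an AP length of
450 um and a DV circumference of 500 um, with the analyzed germband
mask extending 175 um from the ventral midline with a 25-um AP margin.

## The static-source relaxation model

A junction at nematic angle $\theta$ carries myosin $m$ obeying

$$\dot\theta = \rho(\mathbf{x}, t), \qquad
  \dot m = s(\theta)\, s_0(\mathbf{x}) - m/\tau,$$

where $\rho$ is the local tissue rotation rate (half the vorticity of
the tissue velocity field, in deg/min), $s$ is a recruitment source
peaked at $\theta = 0$, and $\tau$ is the effective myosin lifetime.
The intensity-weighted mean deflection $\bar\theta$ of the ensemble then
relaxes as

$$\dot{\bar\theta} = \rho(t) - \bar\theta/\tau,$$

independent of the source's magnitude, spatial modulation and
functional form. Its steady state under constant rotation is
$\bar\theta = \rho\tau$; after rotation ceases it decays as
$e^{-t/\tau}$; and for slowly varying $\rho$ the response lags the
drive by roughly $\tau$. `integrate_mean_deflection()` solves this law
with fixed-step RK4 (default step 0.02 min; the solution matches closed
forms on constant, ramp, and exponential drives to better than
$10^{-6}$ degrees), `predict_deflection_field()` applies it pointwise
on the chart (the default Eulerian mode; a Lagrangian mode that
integrates along advected trajectories is provided because the frame of
integration is a genuine modeling choice, but the two coincide wherever
trajectories circle the vortex cores on which the rotation pattern is
concentrated), and `fit_tau()` estimates the single free parameter.

### The measurement operator in the lifetime fit

The observed myosin orientation field is not pointwise: it is the
intensity-weighted nematic mean of junction orientations within a
20-um disk ("three-cell radius", `anisotropy_field()`). Comparing that
disk-averaged observation with a pointwise model prediction biases the
lifetime fit: smoothing flattens the prediction's spatial peaks where
the data were flattened already. `fit_tau(..., segments = )` therefore
passes the model field through the same disk-averaging operator —
sampling the prediction at the observed junction midpoints and
averaging with the observed intensity weights (a small-angle
linearization of the nematic mean, implemented as one sparse matrix per
frame). This removes the smoothing mismatch; the pipeline and the
acceptance analysis use it by default. A second observation-model
option (`source_width`) maps the linear model mean through the
double-angle (nematic) mean of the stationary model distribution — the
angular source convolved with the exponential-age deflection — before
comparison. The relaxation law describes a linear mean, but the
measured field reports the nematic mean of a distribution confined to
(−90, 90]; in high-rotation cores, where the distribution is broad and
skewed, the two differ by a degree or two, and an uncorrected fit
absorbs that as a shorter lifetime. With both observation-model terms
the five-embryo pooled fit recovers the generating lifetime without
detectable bias. The fit objective is the
weight-averaged absolute nematic deviation over the germband between 10
and 35 min (flow onset to recovery), scanned over a lifetime grid of
0.5-20 min and refined by golden-section search. A flat rotation-rate
history leaves the lifetime unidentifiable and is flagged, never
silently defaulted.

### The lag estimator

`deflection_lag()` reports the lag maximizing the raw (uncentered)
normalized cross-correlation between the rotation-rate and deflection
series; for transient, non-negative signals the zero baseline is
physically meaningful, and the uncentered estimator is insensitive to
how much quiescent time flanks the pulse. On the default wild-type
envelope (ramp 10-20 min, plateau to 25 min, decay by 35 min) with
$\tau = 5$ min the estimator returns 4 min at 1-min sampling; the
continuous-time cross-correlation lag of this drive is about 3.6 min.
The cross-correlation lag systematically undershoots $\tau$ for drives
whose ramps are comparable to $\tau$ — the estimator that equals
$\tau$ exactly for this kernel is the first-moment (centroid) delay —
but we keep the cross-correlation definition because it is the standard
delay measure for noisy series and is the quantity reported for the
embryo data.

## The synthetic embryo

The generator's defaults encode the study conditions; they are not
free dials.

* **Flow** (`flow_spec()`, `make_flow_field()`): four Gaussian-core
  vortices mirror-paired across the ventral midline — a strong
  posterior pair (peak local rotation 5 deg/min at full envelope) and a
  weak anterior pair (1.5 deg/min, below the printed 2 deg/min bound) —
  plus a weak curl-free DV-convergent/AP-extending component, all
  multiplied by a shared piecewise-linear envelope (zero before 10 min,
  ramp to 1 at 20 min, plateau to 25 min, zero by 35 min). Core radius
  55 um and vortex positions at 0.75/0.22 of the AP length place the
  rotation domains so that rotation effectively vanishes in the central
  germband, as observed; only the envelope depends on time, so the flow
  direction is stationary. Exact wild-type speeds in um/min are not
  available; the field is calibrated jointly to the printed rotation-map
  facts (peak values, quiet center).
* **PRG stripes** (`stripe_spec()`, `make_prg_pattern()`): seven
  Gaussian AP bumps (period 40 um, half-width 8 um), DV-modulated with
  a minimum at the dorsal pole (floor 0.1); genes out of register are
  phase-shifted copies. Smoothed gradient magnitude of this pattern
  shows 14 regularly spaced AP bands.
* **Junction ensembles** (`simulate_junction_ensemble()`): persistent
  junction records advect passively with the flow, rotate with the
  local rotation rate, and integrate the myosin balance with a Gaussian
  angular source (width 15 deg) modulated spatially as
  $e^{-d/\ell_m}$ with $\ell_m = 76$ um, chosen so the 10% detection
  floor falls near 175 um from the ventral furrow. Junction lengths
  are fixed (strain does not rotate junctions in this model; pure
  rotation only). Fixed-step RK4, dt = 0.1 min; bit-identical output
  for a fixed seed.
* **Images** (`render_junction_image()`): anti-aliased lines with
  Gaussian cross-section, brightness proportional to myosin, Gaussian
  PSF, additive Gaussian noise (seeded).
* **FRAP traces** (`make_frap_trace()`): immediate-mobile-pool plus
  double-exponential recovery, sampled at 1.5 s — the exact published
  recovery model is not available in the text we work from, so this
  form is a documented stand-in expressing the reported features
  (about 50% immediate drop, fast phase within 30 s, complete recovery
  by 210 s).

What the generator does *not* emulate: cell-resolved junction networks
(junctions are independent segments, so detector clutter from vertices
and curved junctions is absent), intensity inhomogeneities of real
microscopy (bleaching, depth attenuation), non-stationary flow
directions, and strain-driven junction rotation. Passing tests
therefore validate the algorithms under the model's statistical
structure, not the full complexity of light-sheet data.

## Junction detection by windowed Radon transform

`radon_detect()` tiles the image with 12-um windows at 50% overlap.
Per window the median is subtracted and the Radon transform computed at
1-degree steps; each (offset, angle) bin is the mean intensity along
the corresponding chord, multiplied by the square root of its pixel
count so that the noise level is uniform across bins. Peaks at least 5
robust standard deviations above the window median are accepted, where
the scale is the median absolute deviation of the window's own pixels,
floored at 5% of the window's peak excursion (so nearly noise-free
windows threshold against their own signal) and at 1% of the image-wide
maximum (a detection floor: windows far dimmer than the brightest
cannot fire). Non-maximum suppression spans one offset bin and 5
degrees. Each surviving peak is back-projected to its chord, trimmed to
the contiguous run above the half-level, and iteratively refined: the
angle is re-estimated from intensity-weighted second moments in a
2.5-um tube and the run re-trimmed along the refined direction on the
full image (the initial chord is clipped to the window, which shortens
segments and biases midpoints). Duplicates from overlapping windows are
merged when a weaker detection lies within 3 um of a stronger
detection's segment at an angle difference below 10 degrees; weaker
detections within 3 um of a stronger midpoint are treated as angular
sidelobes of the same structure and dropped regardless of angle. On
rendered fixtures with 100 segments at SNR 5 the detector reaches
recall 1.0 with angular RMSE below 5 degrees, and a pure-noise image
yields no detections. All thresholds are exposed in `radon_params()`;
the defaults were tuned on the rendered fixtures, since the original
detector's settings are not published.

Degenerate nematic means — disks whose junctions cancel (order
parameter below 0.05, e.g. equal weight at +45 and -45 degrees) — are
reported as missing (zero weight), never as arbitrary angles.

## Stripe analysis and the gradient regression

Stripe segmentation thresholds the smoothed pattern at half its maximum
and keeps connected components (with DV periodicity) spanning at least
half the germband's DV extent — a deliberately simple substitute for
the interactive pixel classifier used on real images, adequate for
synthetic and well-contrasted data. Inter-stripe lines are intensity
minima between adjacent stripes, one vertex per DV row. The stripe
orientation is the expression gradient rotated by 90 degrees, weighted
by gradient magnitude. Temporal autocorrelation of nematic fields is
the weighted mean of $\cos 2\Delta\theta$ clamped to [0, 1]; the
clamp implements the printed correlation range (anti-aligned maps
to 0), as the exact published formula for nematic fields is not in the
text we work from. Frames with no valid weight yield flagged NA
entries, never a silent 1.

The PRG gradient regression (`prg_regression()`) is ordinary least
squares of the myosin intensity map on the gradient-magnitude maps of
the PRG patterns over the germband, one signed weight per gene and no
intercept (an intercept is available as a flag). Whether the original
analysis used gradient magnitudes or signed components is not stated;
magnitude is the default and components can be passed instead, since
the function accepts arbitrary regressor maps. Rank-deficient sets are
flagged and resolved minimum-norm. The uncentered $R^2$ convention is
used without an intercept.

## Mutant-like parameterizations

`run_config()` presets change only documented knobs relative to wild
type: `twist` halves the flow amplitude; `eve` reduces the lifetime to
2.5 min, the flow amplitude to 0.5 and the source amplitude to 0.6,
moves the flow onset later with a steeper ramp (the published kinetics
change abruptly at 10 min; the envelope break is illustrative), and
widens the angular source to 30 degrees — the last knob is this
package's mechanism for the reduced anisotropy of that genotype, since
a pure amplitude rescaling cannot change the normalized nematic order
parameter; `fat2` extends the DV circumference by 30%, shortens the AP
axis (the intact patterning system compresses onto the shorter egg:
period 34 um), and reduces flow. In Fat2-like geometry the PRG
profile persists toward the dorsal pole while the myosin recruitment
zone still ends near 175 um from the furrow, leaving a stripe zone
without myosin anisotropy.

Pipeline spatial summaries (germband-average angles, per-stripe time
series) are taken over one lateral half of the embryo: the flow is
mirror-symmetric across the ventral midline, so signed angles averaged
over both halves cancel identically, and the published per-stripe
analyses are likewise single-half quantities.

## Numerical choices and problem sizes

Integration uses fixed-step RK4 throughout: 0.1 min for the junction
ensemble, 0.02 min for the scalar relaxation law, 0.25 min for point
advection (0.5 min for whole-field semi-Lagrangian advection in the
pipeline). Interpolation is bilinear in space (DV-periodic, AP-clamped)
and linear in time. Advection is reversible to better than 0.1 um on
the synthetic flows. The lifetime fit in the package's own analyses
uses a five-ensemble pooled observation (matching the five-embryo
ensemble of the study design) with 2000 junctions per ensemble on a
5-um analysis grid; the test suite runs reduced problem sizes (400-800
junctions, 10-um grids) chosen so the full suite completes in a few
minutes while keeping every qualitative contract testable. Monte-Carlo
tolerances in the tests are set from the corresponding standard errors
at those sizes.

## Known limitations

* The Eulerian default of the deflection prediction ignores junction
  transport through the rotation field; on these flows the discrepancy
  is small because trajectories co-rotate around the vortex cores, and
  the residual bias of the recovered lifetime is a few percent.
* The cross-correlation lag under-reads the lifetime for fast ramps
  (see above).
* The lifetime-modulation alternative model is provided for comparison
  (`lifetime_modulation_model()`); the package reports its distribution
  side by side with the static-source prediction and asserts no
  magnitude for the discrepancy.
* The stripe segmenter assumes well-separated, DV-spanning stripes; it
  is not a general-purpose expression segmenter.
* FRAP fitting assumes full recovery (plateau 1); partially immobile
  pools would require freeing the plateau.
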