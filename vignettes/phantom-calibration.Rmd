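---
title: "Calibrating an agar phantom against in vivo CED data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an agar phantom against in vivo CED data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedphantom)
```

## The problem

Convection-enhanced delivery (CED) infuses agents — viral vectors, contrast
agents, therapeutics — into brain parenchyma under a pressure gradient, which
distributes large molecules over volumes that diffusion alone cannot reach.
Planning a CED surgery requires predicting how far a given infusion protocol
will spread in tissue, and animal pilot procedures are costly. A bench-side
stand-in is a transparent agar gel block with brain-like mechanical
properties: dye is infused through the same stepped-tip cannulas with the
same pump schedules, and the growing dye bolus is photographed over time.

The phantom is only useful if it is *calibrated*: the optically measured
distribution volumes must be shown to track the in vivo distribution volumes
measured by MRI with co-infused contrast agent. `cedphantom` implements that
calibration pipeline end to end, together with a synthetic-data generator so
every stage can be validated against known ground truth.

## The quantities

For each infusion trial — bench or in vivo — the primary data are pairs
$(V_i, V_d)$: the cumulative volume pushed by the syringe and the measured
distribution volume of the bolus. Two empirical regularities organise the
analysis:

* within a trial, $V_d$ is close to proportional to $V_i$, so each trial is
  summarised by a **through-origin slope** $V_d/V_i$ (µL/µL), estimated by
  least squares as $\sum x y / \sum x^2$;
* slopes vary between trials, in vivo as much as in gel, so group comparison
  must not assume a common slope.

The calibration model is therefore a **random-slope mixed model with no
intercept**:

$$ V_{d,ij} = (\beta + \gamma\, g_i + b_i)\, V_{i,ij} + \epsilon_{ij}, $$

with $\beta$ the mean slope of the reference group (agar by default),
$g_i \in \{0,1\}$ indicating the other group, $b_i \sim N(0, \tau^2)$ a
per-trial random slope, and no fixed or random intercept — every best-fit
line passes through the origin, since zero infusion means zero bolus. The
**interaction effect** $\gamma$ approximates the difference in average slope
between the groups; a calibrated phantom has $|\gamma|$ small relative to the
spread of slopes. `fit_mixed_model()` estimates this by maximum likelihood
through `lme4`, and returns an object with `print`, `summary`, `coef`,
`predict`, `residuals`, `simulate` and `plot` methods.

When the mixed fit is degenerate — noiseless data, a single point per trial,
zero residual variance — the estimator falls back to per-trial ordinary
through-origin slopes and their group-mean difference; the `method` field
records which route produced the numbers. The two routes agree in the
degenerate limit (with one noiseless trial per group the interaction is
exactly the difference of the two slopes).

## Photograph segmentation

Bench photographs are processed by a deliberately simple, parameterised
chain, mirroring how such images are analysed in practice:

1. **Component extraction** (`extract_component`): one raw 8-bit colour
   channel, no luminance conversion. A yellow dye absorbs blue, so dye
   pixels are *dark* in the blue channel; at higher concentrations green is
   suppressed too. Which channel separates best depends on dye load and
   lighting, so the channel is a calibration parameter.
2. **Thresholding** (`threshold_mask`): pixels strictly below (default) or
   strictly above an integer threshold in 0–255. Ties at the threshold are
   excluded in both directions, so stepping the threshold by one unit moves
   pixels between masks reproducibly.
3. **Cluster selection** (`select_bolus_cluster`): one 8-connected component
   is kept — the seeded one, else the largest. 8-connectivity tolerates
   one-pixel diagonal gaps along thresholded dye edges.
4. **Cannula erasure** (`erase_cannula`): all marked pixels above a manually
   chosen row are cleared (`cut_row` counts rows from the image top). The
   cannula enters from above, so a single horizontal boundary just above the
   tip separates it from the bolus.
5. **Volumetry** (`measure_bolus`): the bolus is modelled as an ellipsoid
   radially symmetric about the cannula axis, $v = \tfrac{\pi}{6} h w^2$,
   with $h$ and $w$ the axis-aligned bounding extents of the mask (in pixels
   spanned, converted by the ruler-derived `scale` in px/mm; 1 mm³ = 1 µL).
   Bounding extents are the simplest defensible reading of bolus "height and
   width"; a fitted-ellipse variant would change little for the convex,
   roughly elliptical masks this pipeline produces.

`segment_series()` runs the chain over a time-lapse series and pairs each
measurement with the protocol's cumulative infused volume at the capture
time. Frames where segmentation fails (no cluster, seed unmarked) are
recorded as missing points, not errors: early frames often lack a resolvable
bolus.

Numerical notes. Pixel-count extents (`max − min + 1`) overestimate a
continuous extent by up to one pixel per dimension, so relative volume error
is roughly $1/h_{px} + 2/w_{px}$; at 10 px/mm and boluses a few mm across
this is a few percent, and it vanishes as resolution grows. The validation
tests therefore use scenes with at least ~50 px across the bolus minor axis
for frame-level 5 % checks, while slope-level checks are insensitive to this
near-constant multiplicative bias.

## MRI bolus extraction

In vivo distribution volumes come from T1-weighted scans in which the
contrast agent (gadoteridol live, Mn²⁺ next-day) is hyperintense.
`extract_bolus_volume()` operationalises the interactive "shrink-wrap ROI"
procedure as a deterministic rule: within a user-placed sphere, voxels at or
above a threshold that are 26-connected to the centre voxel form the bolus;
the volume is the voxel count times the voxel volume, with spacing taken
from the NIfTI header and no resampling. The threshold is chosen per scan,
below the bolus intensity and above the tissue background;
`auto_threshold()` provides a midpoint starting value. Volume by voxel
counting is used rather than an interpolated surface; for the bolus sizes
involved (thousands of voxels) the difference is within the surface-voxel
fraction, which the tests bound explicitly.

## Diffusion-time matching

Next-day scans see a bolus that has also *diffused* overnight, and dye keeps
diffusing through agar after the pump stops — but at a different rate than
in tissue. `match_diffusion()` finds the post-infusion diffusion time at
which the phantom matches a next-day in vivo reference: per-trial volume
series (time measured from infusion end) are smoothed with a centred 3-point
running median — the minimal operator that shifts a selected point off an
isolated noise spike — and the earliest common timepoint at which the
across-trial mean is within a percent-error tolerance (default 5 %) of the
reference mean is reported, or the global minimiser if the tolerance is
never met. The companion `filter_noise()` implements the single-pass rule
used on noisy gel trials: fit a through-origin line to the trial, drop
points strictly greater than 1.1 times the fitted value (one fit, one
removal pass, not iterated).

Whether two in vivo subgroups may be pooled into one reference set is
decided with a two-sided pooled-variance t-test (`pooled_t_test`); the
equal-variance form is the documented contract.

## Calibration as a grid search

The original alignment of phantom to in vivo data was a manual loop: pick a
channel and threshold, segment everything, overlay the curves, adjust,
repeat. `calibrate_segmentation()` replaces that with an explicit grid
search, which is deterministic and reproducible: for every (component,
threshold) pair it segments all agar trials, fits the mixed model against
the reference trajectories, and scores the pair by $|\gamma|$ (absolute
mean-slope difference when the fit is degenerate). Ties are broken by the
lower threshold, then red < green < blue. The returned object carries the
full grid so the flatness of the objective around the optimum is visible.

## The synthetic-data generator

No raw images or scans ship with the package, so `synthgen` renders its own,
with exact ground truth:

* `make_photo_frame()` draws the bench scene — white backdrop, agar block,
  1 mm ruler ticks, vertical cannula, and a dye ellipse of known $h, w$
  below the cannula tip with a mild radial concentration falloff
  ($\alpha = 1 - 0.3 r^4$, keeping the rim strongly dyed so thresholding
  recovers the full extent). The dye suppresses blue most strongly and green
  with concentration, matching the channel choices a real yellow-dye phantom
  motivates.
* `make_photo_series()` grows the true volume along the protocol,
  $v(t) = s \cdot V_i(t)$, and, optionally, continues growth after infusion
  end as a saturating exponential $v_{end}(2 - e^{-t'/\tau})$ — a stand-in
  with the right qualitative behaviour (monotone, decelerating, bounded),
  not a diffusion solver.
* `make_mri_volume()` renders an ellipsoid of elevated intensity over a
  uniform background at arbitrary anisotropic spacing.
* `make_trajectories()` skips imaging entirely and draws trajectory sets
  from the statistical model itself: per-trial slopes
  $N(\mu_g, \sigma_{slope}^2)$, measurements $s\,V_i + N(0, \sigma^2)$.
  Its defaults — 10 trials per group, 20 points per trial over a 50 µL
  infusion, slope spread 0.3 µL/µL, measurement noise 2 µL — are chosen to
  mirror the scale of the bench study's cortical design (7–10 trials per
  group, slopes roughly 2.7–4.8 µL/µL).

All generators are bit-reproducible given a seed, and restore the caller's
RNG state.

What the generator does *not* emulate: optical refraction and specular
highlights in the gel, uneven lighting, reflux tracks, non-ellipsoidal
boluses, partial-volume and bias-field effects in MR, or physically correct
diffusion. Passing round-trip tests therefore validate the *pipeline
mechanics* (geometry, bookkeeping, estimators), not robustness to every
real-world artefact; the calibration grid search exists precisely because
real imaging conditions vary.

## Numerical and design choices

* **Threshold direction** defaults to `below`: physically, dye darkens its
  absorption channel. The opposite direction is exposed as a parameter for
  setups where the bolus is bright.
* **Ties at the threshold** are excluded in both directions (strict
  inequalities), documented so calibration grids partition pixels
  identically across runs.
* **Connectivity** is 8-connected in 2-D and 26-connected in 3-D.
* **Mixed model**: maximum likelihood (not REML) — group comparison is a
  fixed-effect question and ML keeps the interaction and its SE consistent
  with likelihood-based reasoning; no intercepts anywhere, by the physics of
  the origin constraint. The interaction sign convention is non-reference
  minus reference, reference defaulting to agar.
* **Degenerate fits** fall back to per-trial slope means, never to an
  error, so noiseless synthetic data and single-point next-day trials flow
  through the same interface.
* **Step boundaries** in protocols belong to the later step (half-open
  intervals), making piecewise evaluation unambiguous; rates are constant
  within a step.
* **Rounding of reported quantities** follows the conventions of the
  benchmark tables: percent error to 1 decimal, p-values to 2 decimals,
  threshold percentages to integers.

## Problem sizes in the validation suite

The test suite and the acceptance script run entirely on synthetic data at
deliberately desk-scale sizes: photo series of 7–14 frames at 6–16 px/mm,
MRI grids up to 64³ voxels at 0.5 mm, mixed-model simulations of 10 + 10
trials × 20 points, and a 200-replicate null-coverage study. These sizes
were chosen so that the full suite completes in seconds while keeping
discretisation errors within the tolerances being asserted.

## Known limitations

* Ellipsoidal volumetry is exact only for ellipsoidal boluses; irregular or
  refluxed boluses violate the model (real studies exclude such trials, and
  this package provides no automatic reflux detection).
* The pixel scale is user-supplied; there is no automatic ruler detection.
* Voxel-count volumes differ from mesh/interpolated-surface volumes by up to
  the surface-voxel fraction.
* The post-infusion growth model in the generator is phenomenological; do
  not use it to infer physical diffusion coefficients.
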