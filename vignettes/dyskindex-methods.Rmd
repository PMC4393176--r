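---
title: "Methods: the dyskinesia index, LV volumetrics and the motion phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dyskinesia index, LV volumetrics and the motion phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyskindex)
```

## The measurement problem

After a reperfused myocardial infarction, the infarct zone of the
mouse left ventricle loses extracellular-matrix support and can move
*paradoxically*: while healthy myocardium contracts inward during
systole, the weakened wall bulges outward under systolic pressure.
This early dyskinesia both robs the heart of output and predicts
adverse remodeling, so a scalar that quantifies it from routine
high-frequency ultrasound is the core of this package. The raw
measurement is the per-segment radial endocardial displacement track
that a speckle-tracking workstation exports — or, equivalently, traced
endocardial contours from which `dyskindex` computes the same tracks
geometrically.

## The dyskinesia index

Let $d_{i,t}$ be the mean radial displacement of segment $i$
($i = 1 \dots M$, $M = 96$ by default) at frame $t$, with inward
motion positive. The efficiency of wall motion at frame $t$ is

$$\mathrm{eff}(t) \;=\; \frac{\left|\sum_i d_{i,t}\right|}
                              {\sum_i |d_{i,t}|},$$

and the dyskinesia index is the mean of $\mathrm{eff}(t)$ over the
cardiac cycle. When all segments move the same way the numerator
equals the denominator and $\mathrm{eff} = 1$ (completely polar
motion); opposing motion cancels in the numerator but not the
denominator, so the index falls toward 0 as the dyskinetic share of
total motion grows. For fields where every segment follows a shared
waveform $s(t)$ with per-segment amplitudes $A_i$, the waveform
cancels frame-by-frame and

$$\mathrm{DI} \;=\; \frac{\left|\sum_i A_i\right|}{\sum_i |A_i|}$$

exactly — the closed form `analytic_di()` exposes and the numerical
pipeline is validated against.

Two definitional choices deserve comment, because the index's
published verbal description alone does not fix them:

- **Magnitude per time point.** We take the absolute value of the
  *numerator at every frame*, not once on the final average. A raw
  signed ratio would reach $-1$ when most of the wall bulges, which
  contradicts the index's defined range of $[0, 1]$; the per-frame
  magnitude is the only form consistent with both the range and a
  ratio defined "for each time point". A side effect is sign-flip
  invariance: a global inversion of the displacement convention leaves
  DI unchanged, so the inward-positive convention affects only
  reporting, never the index.
- **Zero-motion frames are excluded, not imputed.** At the reference
  frame all displacements are zero and $\mathrm{eff}$ is $0/0$; the
  same happens in any frame whose unsigned sum falls below
  $\varepsilon = 10^{-9}$ mm. Assigning such frames
  $\mathrm{eff} = 1$ (or 0) would shift every DI by an arbitrary
  constant that depends only on frame count, so they are dropped from
  the average and reported in `excluded_frames`. A field with *no*
  usable frame has no DI and raises an error rather than returning a
  default.

The average over frames is unweighted: the acquisitions this targets
(30–40 frames per cycle at effectively uniform spacing) make
time-weighting a no-op to within frame-grid resolution.

## From contours to displacements

The proprietary speckle tracker is replaced by geometry. For one
short-axis slice cine:

1. the reference frame defaults to the end-diastolic frame, detected
   as the frame of maximal endocardial area;
2. the centroid of the *reference* contour (polygon area-weighted
   centroid) is fixed as the origin for every frame — a per-frame
   centroid would translate along with a bulging wall and absorb
   exactly the motion we are trying to measure;
3. each frame's radius is sampled along $K$ rays per angular segment
   ($K = 4$ by default, equal bins counterclockwise from the $+x$
   axis, segment 1 starting at angle 0), a segment's radius being the
   mean over its rays;
4. $d_{i,t} = r^{\mathrm{ref}}_i - r^t_i$, making inward motion
   positive.

Radius-at-angle is computed by exploiting star-shapedness: a contour
is star-shaped about the fixed centroid exactly when its vertex polar
angles are monotone around one turn, which is also the property that
makes "the" radius at an angle well defined. Short-axis LV anatomy
satisfies this; a contour that does not (trace crossing itself past
the centroid) raises an error naming the frame rather than silently
repairing. Anatomical sector labels (anterior, anterolateral, …) are a
presentation-layer regrouping of the 96 segments and deliberately kept
out of the math core.

The ray count matters only through contour discretization: doubling
$K$ moves displacements by less than the vertex-chord error for smooth
contours. At piecewise-constant phantom sectors the residual is
instead dominated by the one edge that spans the sector-boundary
radius jump — visible in tests as a localized, bounded effect.

## Volumetrics, wall thinning

Chamber volume is plain disc summation: slice area (shoelace formula,
orientation-independent) times slice spacing, summed apex to base,
with mm³ ≡ µL. ED and ES are detected **per slice** (area maximum and
minimum, ties to the earliest frame) because infarcted ventricles
contract dyssynchronously; a global-frame mode exists but is off by
default. No partial-volume cap correction is applied — the 1.0 mm
uniform spacing supports plain $A \times h$ summation. EF and SV
follow as identities, with $V_{ES} > V_{ED}$ treated as an upstream
phase-detection error rather than clamped. Longitudinal volume series
are optionally expressed as fold changes of each animal's baseline
(the right scale when groups differ slightly at baseline); EF stays
absolute. Which metrics are normalized is configuration, not
hard-coded.

Wall thickness is measured from paired endo/epicardial traces at end
diastole: the endocardium is resampled at equal arc length and at each
sample the thickness is the distance to the epicardium along the local
outward normal. Normal-ray distance was chosen over nearest-point
distance because it is robust to unequal vertex sampling of the two
traces; for smooth concentric traces the two agree to the chord error.
The thinning extent is the arc-length-weighted percentage of samples
with thickness at or below the threshold — **inclusive** at the
default 0.5 mm, against a normal murine end-diastolic wall of about
1 mm — making the extent monotone non-decreasing in the threshold and
invariant under rigid motion of both traces.

## The motion phantom

`simulate_cine_stack()` generates the study conditions: 6 slices at
1.0 mm spacing, 35 frames per cycle, 96 angular segments, end-diastolic
endocardial radius 1.5 mm tapering linearly by 8 % per slice toward the
apex, wall thickness 1.0 mm. Each segment's radius follows
$r(\theta, t) = R_{\mathrm{slice}} - A(\theta)\, s(t) + \epsilon$ with
$A$ piecewise constant over segments (healthy default $+0.4$ mm,
dyskinetic sectors negative), $\epsilon$ zero-mean Gaussian *radial*
noise — radial because that is the error structure speckle tracking
exhibits and the displacement equation consumes — and $s(t)$ a
raised-cosine systolic waveform peaking at 40 % of the cycle. The
waveform shape is irrelevant to DI oracles (it cancels in the shared-
waveform case) and was chosen smooth to avoid frame-alignment
artifacts elsewhere. All randomness is threaded through explicit
seeds; no global RNG state survives a call.

Between-animal variability in `simulate_cohort()` is per-segment
amplitude jitter with SD 0.08 mm (about 20 % of the healthy
amplitude) — a spread that puts group-level DI standard deviations in
the few-percent range, the order implied by reported treated-group
SEMs in this preparation. Cohort calibration for the two-group
demonstration uses the closed form: a 14-of-96-segment dyskinetic
sector gives $\mathrm{DI} = (96 - 28)/96 \approx 0.708$ (untreated
level) and a 4-segment sector $88/96 \approx 0.917$ (treated level).

What the phantom does **not** emulate: B-mode image formation, speckle
statistics, out-of-plane motion, trace-to-trace observer variability,
breathing/ECG gating artifacts, or any true murine regional amplitude
distribution (the defaults are plausible, not fitted). Passing
phantom tests therefore demonstrates the *analysis chain* — geometry
in, statistics out — not the upstream image processing.

A known bias worth stating: with measurement noise, frames near the
cycle ends carry almost no true motion, their efficiency is dominated
by noise (expected value $\approx 1/\sqrt{M}$), and the cycle average
is pulled slightly below the noiseless closed form. The effect shrinks
with the signal-to-noise ratio and vanishes as noise goes to zero; the
parameter-recovery tests bound it at the stated operating point
(noise SD 0.01 mm, 200 frames).

## Statistics layer

Summaries are mean ± SEM. Group contrasts use the two-tailed
*pooled-variance* Student's t-test (not Welch's — the classical form
this preparation's literature names), and the test suite checks it
against an independently coded closed-form oracle. Longitudinal
metrics over the post-intervention days use a mixed-design ANOVA — one
between-subjects factor (group), one within (time) — via classical
sums of squares with subject as the error stratum for the group
effect, computed by `stats::aov` with an `Error(animal)` term. No
sphericity correction is applied, matching the classical procedure.
Post hoc, per-timepoint group contrasts are Bonferroni-adjusted by the
number of timepoints and capped at 1. Dropout is handled complete-case
(animals missing any included timepoint are dropped with a warning
naming them), the transparent default when the handling is otherwise
unspecified. The suite verifies calibration by simulation: type-I
error of the group effect near 5 % under the null, and near-certain
detection at five within-group SDs of separation.

## Problem sizes and tolerances

The validation suite runs entirely on generated data at these sizes,
chosen to exercise every code path while staying quick on a laptop:
1,000 random 96 × 35 fields for the DI range property; 40 random
noiseless phantoms for oracle equivalence at $10^{-12}$; 50 noisy
replicates (96 segments, 200 frames, noise SD 0.01 mm) for parameter
recovery within 0.02; one full 6-slice contour phantom for the
geometric route (DI within $10^{-3}$, volumes within 0.5 % of the
analytic disc sum); 100 seeded repetitions of the 9-vs-6 cohort
comparison; 200 simulated datasets for ANOVA type-I calibration.
Default ray sampling is 4 rays per segment (384 per contour) against
384-vertex contours.

## Limitations

- DI is a *global* scalar per slice; it localizes nothing. Regional
  maps remain the displacement field itself.
- The contour route requires star-shaped traces; grossly aneurysmal
  geometries violating this are rejected, not approximated.
- Disc summation ignores apex/base partial volumes; comparisons
  across pipelines should use matched slice coverage.
- The RM-ANOVA assumes the classical sphericity conditions; with
  strong violation its time-effect p-values are anticonservative.
- Wall thinning is measured on whichever paired traces are supplied;
  the package does not reconstruct long-axis planes from the
  short-axis stack.
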