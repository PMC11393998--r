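---
title: "Measuring cattle body dimensions from a single side-view depth image"
author: "bovimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cattle body dimensions from a single side-view depth image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovimetry)
```

## The measurement problem

Routine phenotyping of cattle uses four standard dimensions: body height
(withers to hoof), lumbar height, body oblique length (shoulder endpoint
to pin bone), and chest girth. Manual measurement with sticks and tapes
is slow and stressful for the animal. `bovimetry` computes all four from
a single side-view depth image plus seven named 2-D keypoints — Withers,
Sole, Shoulder, Pin, Chest1, Chest2, Lumbar — produced upstream by any
pose detector or by manual annotation. The package deliberately does
*not* detect keypoints; it turns pixel landmarks and a millimeter depth
map into metric dimensions.

## The pipeline

**1. Depth refinement.** Raw depth at a landmark pixel is unreliable:
sensors drop out near silhouettes and report spurious returns. The
refinement anchors everything to a *benchmark depth*: the mean of valid
samples (depths in the open-closed band (0, 7000] mm) in a 3×3 window
around the rounded Shoulder–Pin midpoint, which sits mid-flank where
depth is most stable. Each landmark then receives the depth of the
nearest pixel (concentric Chebyshev rings of growing radius, up to 20 px
by default) whose sample is valid *and* within 500 mm of the benchmark.
A landmark with no qualifying depth within the search radius is reported
missing — never fabricated. A `raster` search mode that replays a plain
nested-loop scan is retained for comparison; it returns the first hit in
scan order, which is generally not the nearest.

**2. Inverse projection.** Qualifying landmarks are lifted to camera
coordinates through the pinhole model, `X = (u - cx) d / fx`,
`Y = (v - cy) d / fy`, `Z = d`. Intrinsics are a mandatory user input
(`readIntrinsics()`); the synthetic camera used throughout the tests
(1280×720, fx = fy = 700) is clearly labelled as such and stands in for
no physical device.

**3. Linear dimensions.** Body height is the Euclidean distance
Withers–Sole, body oblique length is Shoulder–Pin, both in cm = mm/10
with no other scaling anywhere. Lumbar height constructs a ground point
from the lumbar pixel column, the sole pixel row, and the sole's refined
depth (the sole depth encodes the camera-to-ground distance along that
ray), then measures Lumbar to that point.

**4. Chest girth.** The girth plane is sampled along the image segment
from the Chest1 pixel (rear edge of the withers) to the Chest2 pixel
(chest base). Each of the `numPoints` samples gets its own conditionally
filtered depth, so the half-curve follows the animal's visible flank
(`profileMode = "surface"`). The profile is smoothed and densified by
independent multiquadric RBF fits of each coordinate against the sample
index, mirrored to complete the hidden half, closed with an
interpolating periodic cubic spline, and the girth is the polyline
length of the closed loop divided by 10.

## Where the girth design was genuinely open

Three choices in the girth stage deserve explanation, because the naive
composition measurably fails.

**The mirror plane.** Reflecting the visible half-curve across the chord
between its endpoints looks natural but is geometrically wrong at finite
stand-off: a camera at distance $d$ sees a convex section of effective
radius $r$ only up to the tangent rays, an arc of $2\arccos(r/d) < \pi$.
Doubling that arc by reflection under-measures the perimeter by roughly
$\frac{2}{\pi}\arcsin(r/d)$ — 7–10 % at 2–4 m for a cattle torso — and
ties the result to the stand-off distance. The package instead estimates
the *centre* of the girth section and mirrors across its vertical
diameter. Two physical facts fix the frame: gravity makes one section
axis vertical, and a square-on side view aligns the other with the
optical axis. The flank samples therefore satisfy an axis-aligned conic
in camera (Y, Z), fit linearly; the mirror then reduces to a pure
depth-axis flip that maps a front-back symmetric section onto itself.
The same assumption (front-back symmetry of the torso cross-section)
underlies any single-view mirror completion; we only place the plane
where the assumption actually holds. `mirrorHalfCurve()` itself keeps
the plain chord-reflection contract — points on the chord are fixed,
reflection midpoints lie on the chord plane — and a `literal_y` parity
mode that simply negates camera-frame Y is retained for comparison with
pre-centred inputs.

**Robustness of the section fit.** The unconstrained conic fit is
accurate on clean profiles (centre and semi-axes within a few mm of the
generating cylinder) but sits on a curvature ridge: heavy depth noise
can slide the fitted depth semi-axis far out. The fit is therefore
gated: when the profile's own noise estimate (second differences of the
depth along the profile, which on a smooth arc are pure noise) exceeds
3 mm, or the conic result is implausible for a torso (semi-axis ratio
outside 0.4–2.5, axes outside 50–2000 mm), a constrained regression is
used instead — the chord fixes the vertical centre and semi-axis, and
depth is regressed on the ellipse ordinate, a two-parameter fit whose
error scales with noise over $\sqrt{n}$. If neither fit is plausible the
mirror falls back to the endpoint chord.

**Profile density and spline parameterization.** `numPoints` defaults to
150: the profile ends near the silhouette are steep (depth changes tens
of mm per pixel row), and with sparser sampling the mm-quantized depths
drift the section fit by several mm, which doubles into the mirrored
half. The closing spline uses centripetal (square-root chord)
parameterization, which coincides with chord length for evenly spaced
points but damps the outward overshoot of a cubic across the long spans
where the mirrored half joins the sampled half. With these settings the
girth of a noiseless synthetic torso is recovered within 0.7 % at 3 m
and varies by < 1 % over 2–4 m.

A `profileMode = "chord"` parity mode replaces the surface profile with
the straight Chest1–Chest2 segment. Mirroring a straight chord is a
degenerate "there-and-back" loop of about twice the chord length; the
package computes it, but warns, because a flat loop is not a girth.

## The RBF smoother

Algorithm-wise the smoother fits each coordinate as a 1-D function of
sample index with the multiquadric kernel $\varphi(r)=\sqrt{r^2+\varepsilon^2}$
($\varepsilon$ = 1 index step by default) and evaluates on a
`refineFactor`-times denser grid. Two numerical details: smoothing
subtracts `smoothFactor` from the kernel diagonal (the kernel-ridge
convention for this conditionally positive definite kernel; 0 recovers
exact interpolation), and the system carries a linear polynomial tail,
the standard augmentation for a CPD-order-1 kernel. The tail makes
straight-line data reproduce exactly — without it a multiquadric
interpolant of a perfect line deviates visibly between nodes — and turns
the large-smoothing limit into a straight-line fit, which is the
behaviour one wants from "smoothing".

## The synthetic scene generator

Real validation data (live animals, a calibrated depth camera) cannot
ship with a package, so `bovimetry` includes a parametric stand-in with
*analytic* ground truth: an elliptical-cylinder torso (default length
1.5 m, cross-section semi-axes 450 × 350 mm, axis 900 mm above ground —
a medium-frame adult), four vertical cylinder legs, and a ground plane,
ray-cast through the pinhole camera at 1280×720 with the camera ~1 m
above ground and 2–4 m from the flank (the stand-off band where the
method is designed to operate). Depths are the Z coordinate along the
optical axis, rounded to integer mm to mimic 16-bit sensor storage;
background encodes 0. Landmark anchors are placed analytically on the
surface (Shoulder/Pin inset 10 mm from the torso ends so their pixels
are strictly on the body), and true dimensions come from the anchors and
from the torso-ellipse perimeter by adaptive quadrature (`integrate()`,
~1e-10 relative). Sensor noise is modelled as seeded pixel dropout,
circular blob holes, and additive Gaussian depth jitter clamped to
[0, 7000] mm.

What the generator does *not* emulate: articulated posture (standing
only), fur and specular dropout patterns, multi-animal occlusion,
RGB appearance, and the smooth muscle/bone relief of a real topline — a
real withers is a ridge, our torso top is a cylinder apex. Passing tests
therefore demonstrate the geometric correctness and noise behaviour of
the *measurement* pipeline, not detector robustness on real farms.

One bias of the method is visible even on clean synthetic data: the
depth sampled at a topline landmark (Withers, Lumbar, Chest1) is the
depth where the pixel ray *enters* the flank, which at grazing incidence
lies up to ~100 mm nearer than the spine plane. This shifts body height
by about −0.6 to −1.1 % and is inherent to looking up depth at a
silhouette keypoint; the same effect exists on real animals. Body
height recovery on random-model sweeps has a mean relative error of
~0.7 %, with single models occasionally touching 1.1 %.

## Evaluation metrics

For keypoint detectors the package implements object keypoint
similarity, OKS $= \sum_i e^{-d_i^2 / (2 S^2 \sigma_i^2)}\,\delta(v_i>0)
/ \sum_i \delta(v_i>0)$, with $S=\sqrt{\text{bbox area}}$ and a uniform
default $\sigma_i = 0.05$ (cattle-specific sigmas have never been
published; the choice only affects detector evaluation, not
measurement). AP at a threshold is the fraction of detections with OKS
*strictly* above it (0.5 by default; a detection at exactly the
threshold counts as a false positive), and mAP averages AP over
categories — a single category here, so the two coincide. Measurement
accuracy uses MAE and MRE (percent of the manual value), the same
statistics a live-animal validation reports per dimension. Precision is
TP/(TP+FP) and recall TP/(TP+FN).

## Degenerate inputs and numerical conventions

* Depth 0 always means "no measurement"; 7000 mm is a *valid* depth
  (the band is open at 0, closed at 7000); the 500 mm benchmark
  tolerance is inclusive.
* Pixel coordinates are zero-based (column u, row v), sub-pixel allowed;
  depth lookup rounds half away from zero.
* The Shoulder–Pin midpoint is rounded half away from zero; an empty
  3×3 reference window is an error unless `growReference` doubles it (at
  most three times).
* Ring search ties break by scan order: increasing row offset, then
  column offset.
* Consecutive duplicate points are removed (1e-6 mm) before spline
  fitting; fewer than 4 survivors is an error; a singular RBF system is
  re-solved with a small diagonal regularizer rather than failing
  silently.
* Missing landmarks make the affected dimension NA with a named note —
  never zero, and never blocking the other dimensions.

## Problem sizes used in the test suite

The suite renders 1280×720 scenes (about 0.9 s each): one canonical
scene shared across tests, a 10-model random sweep at 3 m, a three-point
distance sweep (2, 3, 4 m), and a four-level jitter ladder
(0/5/15/30 mm, three seeds each). These sizes keep the full suite around
two minutes while still exercising every stage end-to-end against
analytic truth.
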