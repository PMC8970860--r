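---
title: "Measuring ocular deviation from nine-gaze photographs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular deviation from nine-gaze photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strabmetric)
```

## The measurement model

strabmetric measures ocular deviation on the Hirschberg principle: the
corneal light reflex (the specular reflection of a flash on the cornea) is
a stable anchor tied to the eyeball's optical axis, so the pixel distance
between an eye's limbus center and the reflex point quantifies how far the
eye has rotated.  Across the nine cardinal gaze positions this yields a
per-direction excursion profile; paretic muscles show up as shortened
excursions in their direction of action.

Three modeling assumptions make the 2-D measurement tractable:

1. limbus and sclera project as circles;
2. in adults the sclera (eyeball) radius is 2.5 x the limbus radius — this
   ratio is exposed as `sclera_limbus_ratio` because it is an adult
   average and the package has no pediatric correction;
3. the reflex axis passes through the eyeball center, so the reflex point
   detected in the primary gaze remains the reference for every eccentric
   gaze.  No per-gaze reflex detection is performed: eccentric reflexes
   slide off the cornea and are unreliable, and the deviation measure is
   defined against the primary-gaze anchor.

The pixel distances themselves carry no direct clinical unit (no
prism-diopter conversion is attempted); the clinically interpretable
output is the *ratio* of impaired to reference excursion, reported in
percent.

## Registration

Eccentric frames are mapped onto the primary frame with a two-point
similarity transform. The landmarks are the innermost (nasal-most) points
of the two sclera regions — in a face, the medial canthi — which are
rigidly attached to the head rather than to either rotating eyeball.  The
segment joining them gives a center, length and angle; matching those to
the primary frame's segment fixes translation, isotropic scale and
rotation.  Scale and rotation pivot about the moving segment's center and
the translation moves that center; any other self-consistent convention
yields the same transform, since four scalar constraints (two 2-D
endpoints) determine a similarity exactly.  Images are warped with
bilinear interpolation, masks with nearest-neighbor so they stay binary;
out-of-bounds pixels fill with background.

Pixel-level landmarks quantize each coordinate to ±0.5 px, and with only
two landmarks that noise propagates undamped into the transform (≈1 px
displacement at the limbus after a 1 px landmark error on a ~100 px
baseline).  The pipeline therefore refines each landmark to subpixel
precision as the centroid of the foreground pixels within 1.5 px (along
x) and 2.5 px (along y) of the extreme pixel — the canthus-tip
neighborhood.  The tight y-window matters under camera roll: a wide window
would mix in boundary pixels of the eyeball disk far from the rotated tip.
`innermost_points(refine = FALSE)` (the default) still returns the exact
extreme pixel with the documented tie rule (minimal y, then minimal x),
which is the operation's contract; `refine = TRUE` is what
`scene_reference_line()` and the pipeline use.

## Eccentric limbus recovery

In an eccentric gaze the visible limbus is foreshortened and often
truncated, so its enclosing circle is biased.  Instead, an ellipse is
fitted to the limbus boundary with the direct least-squares conic method
(Fitzgibbon's ellipse-constrained fit in the numerically stable
Halir–Flusser form): deterministic, initialization-free, exact on true
ellipse samples.  Two numerical details:

* **Half-pixel compensation.**  Boundary *pixel centers* of a rasterized
  ellipse lie on average half a pixel inside the continuous outline, so
  fitted semi-axes are inflated by 0.5 px for mask input.  Without this
  the semi-minor axis of a 20 px ellipse is underestimated by ~2.5 %.
* **Fit in the native frame.**  A similarity transform commutes with
  ellipse fitting, so the pipeline fits each limbus in its original frame
  and maps the fit through the registration transform
  (`transform_ellipse()`), rather than fitting on a nearest-neighbor
  resampled mask.  The results agree in exact arithmetic; the native-frame
  fit avoids resampling aliasing.

The limbus center is then re-assigned along the short (minor) axis: from
each of the two minor-axis boundary points, step one limbus radius R back
along the short-axis extension line.  This yields two candidates,
`center ± (b − R)·u` with semi-minor b and minor-axis direction u.  The
construction's geometric rationale: the outer elliptical contour still
touches the true limbus outline, so the true center lies R inside it along
the foreshortening direction.  Of the two candidates the one closer to the
modeled eyeball center is returned — the limbus center must lie on the
eyeball.  In the perfectly symmetric tie (fit center coincident with the
eyeball center) the candidate displaced toward +x (toward +y for a
vertical short axis) is chosen, a documented deterministic convention.  If
both candidates fall outside the eyeball circle the geometry is
inconsistent and an error is raised.

Near the primary gaze the limbus is almost circular and the minor-axis
direction is numerically meaningless, so for minor/major >
`circularity_threshold` (default 0.95) the fit center is used directly.
The continuity of this fallback is tested: as the simulated foreshortening
goes to zero the recovered center converges to the fit center.

## Reflex detection

Within the limbus mask, pixels at or above `reflex_threshold` (default
0.9) of the in-mask maximum form the candidate blob; the largest
8-connected component's intensity-weighted centroid is the reflex point.
An absolute floor (`reflex_floor`, default 0.8 of the dynamic range)
guards against latching onto iris texture when no true reflex is present
— a primary gaze without a detectable reflex in each eye is a hard error,
because the whole measurement is anchored on it.

## Segmentation metrics

Accuracy, sensitivity and specificity are the usual confusion-matrix
ratios in percent.  DSC is the standard Dice coefficient
`100 · 2TP / (2TP + FP + FN)`.  A variant normalizing by the total pixel
count (`2TP / (TP + TN + FP + FN)`) circulates in some write-ups but is
not the Dice coefficient and is inconsistent with the ~96 % values such
write-ups report alongside the other metrics; it is available behind
`dice_printed_variant = TRUE` purely for auditability and is off by
default.  Ratios with zero denominators are reported as `NA`, never 0.
Connected components use 8-connectivity throughout.

## The synthetic world

`make_nine_gaze_set()` renders what the measurement needs and nothing
more: two flat eyeball disks (radius exactly 2.5 x the limbus radius) on
a horizontal midline, limbus disks displaced by per-gaze offsets, a 2 px
near-white reflex blob at the primary limbus center, and intensity levels
(background 0.1, sclera 0.75, limbus 0.35, reflex 0.98) that give the
reference threshold segmenter unambiguous bands.  Defaults: 512 x 512
scenes, limbus radius 24 px, eyeball centers ±110 px from the facial
midline, healthy excursion 30 px (≈7 mm at this crop scale, a full
excursion), per-frame camera jitter uniform in scale 0.9–1.1, roll ±10°,
translation ±20 px.

Two deliberate departures from the most naive rendering:

* **Medial canthus landmark.**  A bare disk has no usable "innermost
  point": its rasterized horizontal extreme is a tall chord (±8 px at
  radius 60) whose tie-broken top jumps with subpixel alignment, and the
  extreme of a *rotated* disk does not rotate with the scene.  Under
  camera roll θ this produces an irreducible common-mode registration
  error of `2 r sin(θ/2)` (≈10 px at 10°) — the measurement would be
  degenerate not because the algorithm is wrong but because the world
  lacks the anatomy the algorithm relies on.  The renderer therefore adds
  a small blunt-tipped canthus wedge (apex `canthus_px = 2` beyond the
  disk, half-width ≥1.25 px so the tip always contains pixel centers)
  pointing at the facial midline and rotating with the scene.  This is a
  landmark, not an eyelid model; `canthus_px = 0` restores pure disks.
* **Analytic jitter.**  Jittered frames are rendered from the transformed
  geometry rather than by warping the primary raster: a jittered camera
  re-images the continuous scene, and nearest-neighbor warping would
  resample away the subpixel canthus tip.

What the generator does **not** emulate: eyelid occlusion and partial
limbus truncation, perspective foreshortening of eccentric limbi (the
flat-disk limbus stays circular, so the short-axis recovery path is
exercised by purpose-built elliptical fixtures rather than by the
renderer), iris texture, illumination gradients, and sensor noise
(available via `noise_sd` but off by default).  A green end-to-end test
therefore establishes that the measurement chain is correct on geometry
satisfying its own assumptions — not that a particular segmenter works on
clinical photographs.

The palsy presets scale excursions of the affected eye and direction:
`CN4_bilateral` scales each eye's downward-inward excursion (default
ratio 0.9), compared within-eye against downward-outward;
`CN6_left` scales the image-left eye's outward excursion component
(default ratio 0.3), compared between-eye for the same direction.  The
two comparison schemes mirror the two clinical presentations and are
expressed in the same declarative `comparison_spec` mechanism users
configure for real data — which gaze pair quantifies a deficit is a
clinical choice, so the package ships the mechanism plus presets rather
than a fixed table.

## Conventions, rounding, degenerate inputs

Pixel coordinates have their origin at the top-left pixel center, x
rightward, y downward, subpixel positions as reals; masks are rasterized
by center-of-pixel inclusion.  "Left eye" means the image-left component
(smaller centroid x); `anatomical_laterality = TRUE` mirrors the labels.
Angles are degrees, reference-line angles normalized to (−180, 180],
ellipse orientations to (−90, 90].  Distances are reported as integer
pixels and percentages to one decimal (presentation only; internal math is
full precision).  Degenerate inputs raise classed conditions
(`strab_degenerate_mask`, `strab_invalid_geometry`, `strab_no_reflex`,
`strab_geometry_inconsistency`, `strab_spec_error`) with the offending
gaze attached by the pipeline.

## Known limitations

The two-point similarity registration cannot absorb out-of-plane head
rotation; the 2.5 ratio is an adult average; measurement noise of ±0.3–
0.5 px per distance translates into a few percentage points of ratio noise
when excursions are small (a 9 px impaired excursion carries ~±3 points);
and very small or mostly-occluded limbi are out of the synthetic world's
scope.  Pixel distances are not convertible to deviation angles without a
3-D eye model, which this package intentionally does not include.
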