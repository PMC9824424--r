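---
title: "Non-destructive cabbage morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-destructive cabbage morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabbagemorph)
```

# The measurement problem

Head volume and total leaf area are the two plant-level quantities that
growers of head-forming brassicas most want to track: both correlate with
nitrogen status and predicted yield, and both are conventionally obtained
destructively (harvest, strip the leaves, tape-measure the head). This
package implements an image-based alternative that works from two inputs a
field imaging rig can produce non-destructively:

* per-instance segmentation masks for three classes — the whole **plant**,
  the cabbage **head** (the crop organ), and each visible **leaf** — and
* a co-registered **depth raster** (camera-to-surface distance in mm)
  from photogrammetry, with pinhole camera intrinsics.

How those masks are produced (a trained network, hand annotation) is out of
scope: masks are inputs here. The package's own contributions are the
geometry and allometry downstream of segmentation, an evaluation module for
segmentation quality, and a synthetic scene generator that makes every
stage testable without field data.

# Coordinate conventions

One fixed convention prevents sign errors across modules. Image pixels are
0-based `(col, row)` with the origin at the top-left. The world frame puts
`z = 0` on the ground plane with `z` up, `x` along +col and `y` along +row;
the camera looks straight down (nadir) from `camera_height` (default
900 mm, a typical boom height for row crops). Depth is the distance from
the camera *along the optical axis*, which is what multi-view-stereo depth
maps store, so surface height is `camera_height - depth`. Back-projection
of a pixel `(col, row)` with depth `d` is the pinhole rule

$$x = (col - c_x)\,d/f,\qquad y = (row - c_y)\,d/f,\qquad
z = h_{cam} - d .$$

An orthographic mode (`x = col * gsd`) exists purely to make analytic test
cases trivial.

# The leaf-attachment point

All leaves of a cabbage converge at the stem, but that attachment point is
never visible from above. The estimator exploits the convergence itself,
in three steps per plant:

1. **Robust cleaning.** Each leaf's back-projected point cloud passes
   through MSAC (M-estimator sample consensus): random 3-point candidate
   planes are scored by the *truncated* squared orthogonal residual
   $\sum_i \min(r_i^2, \tau^2)$ and the best plane's inliers (within
   $\tau$) are kept. The truncated loss makes MSAC prefer tight planes
   rather than merely populous ones, which matters for thin, gently curved
   leaves. When the cloud is small enough that all 3-subsets fit in the
   iteration budget they are enumerated, making the result independent of
   the seed.
2. **Regression plane.** A least-squares multiple linear regression of `z`
   on `(x, y)` fits `z = ax + by + c` to the inliers. Vertical residuals
   are the right choice here (rather than orthogonal ones) because the
   camera looks down: depth error lives in `z`. The plane extends the
   leaf's orientation inward, past its visible edge, towards the stem.
3. **Intersection voting.** Three planes in general position meet in a
   point, so every unordered triple of leaf planes is solved as a 3×3
   linear system. "Intersections" are read as *triple* intersections
   because plane pairs meet in lines, which admit no canonical point to
   average. A triple is discarded when (a) the determinant of the
   row-normalised system matrix is below `stem.det_threshold` (default
   `1e-6`; near-parallel planes otherwise send the solution arbitrarily
   far away), (b) the solution projects outside the segmented plant area,
   or (c) its height leaves `[0, camera_height]` — points below ground or
   above the camera are artefacts. The surviving points are averaged
   (arithmetic mean; a median option exists behind
   `stem.aggregate = "median"` for robustness experiments but is not the
   default, since the mean is the published procedure). One shared
   attachment point serves all leaves of a plant: per-leaf variants were
   reported to deviate badly because inner leaves are dome-shaped rather
   than funnel-shaped.

On exactly planar synthetic leaves with no noise this chain recovers the
attachment point to solver precision; the test suite asserts `< 1e-6` mm
with the mask filter disabled and `< 1` mm end-to-end through the renderer.

# Leaf length and the area allometry

The endpoint of a leaf is simply the cloud point farthest (3D Euclidean)
from the attachment point, and the leaf length `L` is that distance.
Curvature is deliberately ignored — the straight chord is robust to the
partial visibility that dooms curvature-following estimates in a closed
canopy. With a nadir camera the leaf *width* is unobservable for the outer
leaves, so the area rule substitutes the plant's mean leaf length
$\bar{L}$:

$$A_i = \bar{L} \cdot L_i \cdot 2.7 \quad (\text{mm}^2 \to \text{m}^2),
\qquad LA = \sum_i A_i = 2.7\, n \bar{L}^2 .$$

The shape factor 2.7 (`leafarea.shape_factor`) is an empirical constant
for storage cabbage; the closed-form identity on the right is asserted on
random inputs in the tests. Only *visible* leaves enter the totals — no
hidden-leaf correction is applied, matching the published behaviour — and
a leaf belongs to a plant only when more than 80% of its area
(`assign.threshold`) lies inside that plant's mask; ambiguous leaves go to
the largest overlap fraction, exact ties to the lower plant id, and
below-threshold leaves are reported as unassigned rather than guessed.

# Head volume

The segmented head area (pixel count) is treated as the head's
cross-section: the equivalent-circle radius is $r_{px} = \sqrt{A/\pi}$.
An area-based radius, unlike an outline fit or a sphere-RANSAC in depth,
degrades gracefully when leaves hide part of the rim. Conversion to
millimetres must happen at the *equator's* distance `H`, not the apex's:
with apex distance $Z_0$ (the 5th percentile of in-mask depths,
`head.apex_percentile`, robust to depth speckle) the coupled system
"equator = apex + radius" has the closed-form solution

$$r_{mm} = \frac{r_{px} Z_0}{f - r_{px}}, \qquad H = Z_0 + r_{mm},$$

and the volume follows the sphere model $V = \tfrac{4}{3}\pi r^3$. The
conversion-rule form `r_mm = r_px * H / f` is the physically consistent
pinhole reading (mm per pixel grows with distance); a literal reciprocal
form `r_px * k / H` is selectable via `head.eq5_mode = "literal"` for
sensitivity analysis only, because the printed form of that conversion is
dimensionally ambiguous. The ground-truth helper
`volume_from_circumference()` applies the same sphere model to a tape
measurement, `radius = circumference / 2π`.

**Known bias.** The segmented disc is the sphere's *outline*, whose
projected radius exceeds the equator's projection by the factor
$Z_c/\sqrt{Z_c^2 - r^2}$, and the percentile apex sits $r(1-\sqrt{0.95})$
beyond the true apex. Both biases are positive and grow with $r/Z_c$; at a
900 mm camera height the recovered volume of an unoccluded synthetic head
is a few percent high, reaching roughly +6% at `r = 120` mm. The tests
assert 3% only for small heads (`r <= 75` mm) and 8% across 60–120 mm, and
the end-to-end tolerance under ≤ 30% occlusion is 15%. Estimating the
radius from the outline geometry directly would remove the bias but would
no longer be the method this package sets out to reproduce.

# The synthetic scene generator

`build_scene()` / `render()` emulate exactly the study conditions the
measurement chain assumes:

* a funnel plant of 10–25 **planar elliptical leaves** whose inner tips
  touch the attachment point, azimuths equally spaced with ±5° jitter,
  tilted 25° above horizontal by default; lengths uniform in 150–350 mm,
  widths 0.6 × length (capped at the length so the far tip is the leaf's
  farthest point from the base);
* an optional **spherical head** tangent from above to the attachment
  height (omit it for the earliest growth stage, where no head exists);
* a pinhole **z-buffer render** at the study camera (900 mm height;
  f = 1000 px and a 1024×1024 frame as defaults, since the rig's
  intrinsics are not published) producing the depth raster and the three
  label maps, with additive Gaussian depth noise (default sd 2 mm, a
  plausible close-range photogrammetry figure) and optional uniform gross
  outliers replacing a fraction of pixels;
* `occlude_head()` adds horizontal leaf patches just above the apex until
  a requested fraction of the head's image disc is hidden, measured in
  image space while placing patches.

Leaves are planar because the measurement model itself ignores curvature —
planar truth makes length recovery exactly checkable. Real SfM data differ
in ways the generator deliberately does not mimic: spatially correlated
reconstruction error, mixed pixels at depth discontinuities, specular
failure on wet leaves, and weed clutter. Passing the synthetic recovery
tests therefore demonstrates the geometry is implemented correctly, not
that field accuracy will match. Note also that the generator's elliptical
leaf area $\pi ab$ is *not* what the allometric rule estimates; tests
compare lengths against truth exactly but compare areas only through the
allometric identity.

`render()` returns two kinds of head mask: the visibility-clipped mask a
detector would produce, and a `head_masks_full` variant covering the full
projected outline, emulating how a human annotator outlines a partially
covered head. Occlusion experiments use the full mask — with the clipped
mask a 30% cover would remove 30% of the area and so ~44% of the volume,
which is a property of the input convention, not of the estimator.

# Evaluation module

Segmentation quality uses the COCO instance-evaluation conventions:
mask IoU; greedy score-descending matching with per-truth exclusivity at a
given IoU threshold; average precision by 101-point interpolation of the
precision envelope; and mAP as the mean AP over thresholds 0.50–0.95 in
steps of 0.05. The published evaluation names these metrics but not the
integration rule; the COCO dialect is chosen because the segmentation
models in this domain are COCO-pretrained and benchmarked that way.

Two statistics helpers mirror the reference tables' footer conventions:
`column_stats()` uses the *population* standard deviation (divisor *n*) —
this choice, and not the sample SD, reproduces the printed SD of the
bundled volume table from its own column — and `accuracy_stats()` is the
mean over items of `100 * (1 - |est - ref| / ref)`, floored at zero. The
source never states its accuracy formula; on the bundled BBCH-48 volume
table this reading gives ≈ 86.6% against a printed 87.2%, a discrepancy we
report rather than tune away (the printed value was presumably computed
from unrounded per-plant data).

# Bundled reference tables

`cabbage_tables()` ships the per-plant validation tables of a destructive
field study of 30 storage cabbages (10 per growth stage BBCH 41/45/48):
hand-measured head volumes and visible leaf areas next to the image-based
estimates from ground-truth masks ("calculated") and detected masks
("detected"). `reproduce_tables()` recomputes every summary statistic from
the per-plant rows and lays it beside the printed summary row. A handful
of printed summaries disagree with their own columns in the last digit
(the note column flags each one); the comparison keeps both numbers
visible instead of silently preferring either.

# Numerical choices and degenerate inputs

* MSAC: tolerance 10 mm (order leaf thickness + depth noise), 500
  iterations, seed mandatory in any scripted run; all-collinear samples
  raise a degenerate-geometry error; inlier support below
  `min_inlier_fraction` (0.5) attaches a `low_support` flag and warning.
* Plane fits require ≥ 3 points with non-collinear `(x, y)` (QR rank
  check).
* Triple intersection: row-normalised determinant threshold `1e-6`;
  z-plausibility `[0, camera_height]`.
* Leaf endpoint ties break to the first point in scan order, making runs
  reproducible.
* Per-plant failures inside `measure_scene()` become error records, and
  leaves with fewer than 3 valid depth pixels are listed as `skipped`, so
  batch runs over a field complete and account for every instance.
* Problem sizes in the tests: recovery scenes render one 12-leaf plant at
  1024×1024 (about 0.5 s per render); coarser 360×360 scenes serve the
  geometry-only properties. These sizes make the whole suite run in well
  under a minute while leaving rasterization error an order of magnitude
  below the asserted tolerances.

# Limitations

* The sphere model is specific to round-headed cultivars; pointed or flat
  heads need a different solid.
* The allometric factor 2.7 is cultivar-calibrated; transferring it
  unvalidated to another brassica changes the LA scale.
* Leaf lengths are chords; strongly curled leaves are under-measured by
  construction.
* The head-volume estimator carries the positive outline/percentile bias
  quantified above.
* Only uncompressed-RLE and polygon COCO segmentations are supported.
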