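# cabbagemorph

Non-destructive estimation of cabbage head volume and total leaf area from
top-down instance-segmentation masks and a co-registered depth raster.

Measuring a cabbage the classical way destroys it: the head is harvested
and tape-measured, the leaves stripped and scanned. This package
implements the image-based alternative for users who already have (a)
per-instance masks for three classes — whole *plant*, cabbage *head*, and
each visible *leaf* — from any segmentation source, and (b) a depth map in
millimetres from close-range photogrammetry, plus pinhole intrinsics. It
is aimed at plant-phenotyping and precision-agriculture researchers who
want per-plant morphometry out of nadir field imagery.

## Method

**Leaf-attachment point.** All leaves of a plant converge at the stem, but
the attachment point *p* is hidden. Each leaf's back-projected point cloud
is cleaned by MSAC (truncated-loss sample consensus, score
Σ min(r², τ²)) and fitted with a regression plane *z = ax + by + c*;
every triple of leaf planes is intersected (3×3 solve), intersections are
filtered to the segmented plant area and plausible heights, and their mean
is *p*.

**Leaf length and area.** A leaf's endpoint *q* is its cloud point
farthest from *p*; its length is L = ‖q − p‖ (curvature deliberately
ignored). Because leaf width is unobservable from above, the area uses a
length-based allometry with the plant's mean leaf length L̄:

    A_i = L̄ · L_i · 2.7   (mm² → m²),    LA = Σ A_i = 2.7 · n · L̄²

**Head volume.** The segmented head area gives an equivalent-circle radius
r_px = √(area/π). With apex distance Z₀ (5th percentile of in-mask
depths), the metric radius solves the coupled apex/equator system in
closed form, r_mm = r_px·Z₀/(f − r_px), and the volume is the sphere model
V = (4/3)·π·r³.

**Evaluation & validation.** COCO-style mask metrics (IoU, greedy
matching, 101-point AP, mAP over IoU 0.50–0.95), summary statistics
matching the bundled field-validation tables of 30 storage cabbages at
growth stages BBCH 41/45/48, and a synthetic scene generator (planar
elliptical leaves in a funnel + spherical head, z-buffer rendered with
depth noise and outliers) whose ground truth makes every stage testable.
See the methods vignette (`vignettes/cabbage-phenotyping.Rmd`) for
assumptions, parameter defaults and known biases.

## Worked example

```r
library(cabbagemorph)

cam   <- camera_model()                 # nadir, 900 mm height, f = 1000 px
scene <- build_scene(plant_spec(n_leaves = 12, head_radius = 90),
                     cam, seed = 7)
rd    <- render(scene, noise_sd = 2, outlier_fraction = 0.05)

measures <- measure_scene(rd$leaf_masks, rd$plant_masks, rd$head_masks,
                          rd$depth, cam)
measures
#> <scene_measures> 1 plant(s), 0 unassigned leaf(s), 0 error(s)
#> <plant_measure> plant 1: 12 leaves, mean length 232.6 mm, LA 1.754 m^2, head 90.7 mm / 0.00313 m^3
measures$plants[[1]]$attachment
#> <attachment_point> (0.1, -0.1, 50.2) mm, support 220, dispersion 1.02 mm
```

The generator's truth for this scene is an attachment point at
(0, 0, 50) mm, a 90 mm head of volume 0.00305 m³, and leaf lengths between
150 and 350 mm: despite 2 mm depth noise and 5% gross outliers, the
attachment point is recovered to a fraction of a millimetre (220 of the
C(12,3) plane triples survive the filters; their RMS scatter is ~1 mm),
every leaf length to well under 1%, and the head volume to ~3%. The total
LA of 1.754 m² is the allometric estimate 2.7·n·L̄², not the elliptical
truth — the difference is the allometry's modelling error, which is the
quantity the bundled validation tables characterise on real plants.

`reproduce_tables()` recomputes every summary statistic (means, population
SDs, cross-column mean accuracies) from the bundled per-plant reference
tables and lays them beside the printed summary rows; a `note` column
flags the few printed entries that disagree with their own columns.

A thin CLI wraps the same functions for shell use:

```sh
exec/cabbage-morph simulate --out-dir scene1 --seed 3 --plants 1 --noise 2
exec/cabbage-morph measure-scene --leaf-map scene1/leaf_map.tif \
    --plant-map scene1/plant_map.tif --head-map scene1/head_map.tif \
    --depth scene1/depth.tif --out scene1/measures
exec/cabbage-morph table-stats --csv inst/extdata/volume_bbch48.csv \
    --column measured_m3
```

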