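---
title: "From MRI segmentation to a slice-registered sectioning mold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From MRI segmentation to a slice-registered sectioning mold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiregional tumor sampling after nephrectomy is usually blind: by the time
the pathologist cuts the specimen, image guidance is gone, so tissue blocks
cannot be traced back to the imaging voxels that motivated them. A
patient-specific 3D-printed mold solves this by holding the resected
specimen in a known orientation and channelling the knife through vertical
slots whose positions coincide with chosen imaging slice locations. Renal
specimens add two complications that drive the whole design: the pathology
protocol dictates cutting along or transverse to the kidney's long axis
(not along the MRI acquisition planes), and the specimen arrives wrapped in
perinephric fat that hides every anatomic cue, so the mold itself must
encode how the specimen sits in it.

`moldkit` turns a presurgical segmentation (tumor, normal kidney,
perinephric fat — their union is the specimen outline) plus five anatomic
landmarks (kidney poles, hilum, tumor and kidney contact points) into a
watertight, printable mold mesh, and validates the result geometrically.

## Sectioning frame

Let $u$ and $l$ be the upper and lower pole positions and $c$ the tumor
centroid, with $a = (u - l)/\lVert u - l \rVert$ the long-axis direction.
The knife-plane normal (the direction in which slices stack) is

* **transverse** mode: $n = a$ — cuts perpendicular to the long axis;
* **longitudinal** mode: $n = a \times (c - l) / \lVert \cdot \rVert$ —
  cuts parallel to the plane containing the long axis and the tumor
  centroid, so the central cut through $c$ also contains both poles.

The remaining degree of freedom is the roll about $n$. The hilum and the
tumor contact point must end up at the mold base, where 2-cm holes let the
pathologist see and feel them to confirm the specimen is seated correctly.
The roll angle is found by exhaustive search on a 1° grid, minimizing the
summed height of the two anchor landmarks above the lowest point of the
outline. Two numerical details matter here:

* the "lowest point" is evaluated on sub-voxel vertices of the outline
  surface (the mask smoothed by one voxel, then iso-surfaced), because the
  support function of a raw voxel set is up to half a voxel smaller along
  oblique directions, which would bias the optimum by 10° or more;
* even so the objective is flat near its minimum, so the resolved angle is
  reproducible only to a few degrees — irrelevant at the scale of a 2-cm
  anchor hole, but the reason the tests assert the *objective value*, not
  the angle.

A closed-form roll was deliberately not attempted: the objective depends on
the outline's support function, which has no usable closed form for real
anatomies, while the 1° grid is exhaustive, testable and costs well under a
second.

All masks are then resampled by nearest neighbour (labels must stay labels)
onto an isotropic 1 mm lattice whose axes are (normal, lateral, up);
parameter maps, if present, are resampled trilinearly. 1 mm is
sub-millimetric relative to consumer printer accuracy while keeping the
default phantom inside a few million voxels. The lattice phase is anchored
to voxel centers, so an axis-aligned resampling is exactly the identity.

## Building the mold

Carving happens in voxel space — boolean operations on an occupancy grid
are robust and directly testable, unlike mesh CSG — and the printable
surface is extracted once at the end:

1. **Outline smoothing.** The binary outline is blurred with an isotropic
   Gaussian ($\sigma$ = 2 mm by default) and re-thresholded at 0.5. This
   removes voxelization steps before the cavity floor is derived. The
   level-set view predicts a curvature-dependent erosion of about
   $\sigma^2 H$ (mean curvature $H$); for a 20-mm sphere that is a 3%
   volume loss, which the unit tests assert as the *expected* behaviour
   rather than treating volume preservation as exact.
2. **Block and cavity.** The block is the outline footprint dilated
   laterally by 10 mm, extruded to base (10 mm) + outline height; the +lateral
   face is flattened and extended 15 mm to carry the guide comb. The cavity
   is carved by *vertical shadow*: every column that meets the outline is
   emptied from the outline's lowest surface upward. The resulting cavity
   is open-top and overhang-free by construction, so a rigid specimen can
   always be lowered in; the price is that concavities of the *lower*
   surface are bridged. A single-sided mold was chosen over a two-part one
   for exactly the reason the design targets fat-covered specimens: the
   upper half of the specimen is unconstrained anyway.
3. **Slots and guides.** Knife slots (2 mm wide, stopping 5 mm above the
   block bottom so the mold stays in one piece) are cut at the slice-plan
   positions: planes at `offset + k * spacing` covering the tumor extent
   plus one margin plane per side, labelled from the lower end. When the
   source affine is available the offset is phased so the plan coincides
   with original imaging slice centers. Guide teeth between slots carry
   k tick-mark notches on tooth k as a printable numbering surrogate.
4. **Anchor holes.** Two vertical cylinders (20 mm diameter) are drilled
   through the base at the (s, l) positions of the hilum and the tumor
   contact point. A hole that would come within 2 mm of the outer wall is
   refused with an error naming the landmark.
5. **Meshing.** The occupancy grid is blurred by half a voxel (this also
   removes the rare corner-touching voxel configurations that would pinch
   the surface into a non-manifold edge), iso-surfaced by marching
   tetrahedra, decimated to 20k faces by quadric edge collapse and given
   two Taubin $\lambda|\mu$ passes. Marching tetrahedra was preferred over
   the classic cube table: it needs no 256-case table, and its surface is
   closed and consistently oriented by a permutation-parity argument that
   holds even for degenerate slivers. Longer Taubin runs (the conventional
   10+) were measured to inflate the mold volume by up to 17% — uniform-
   weight smoothing rounds the mold's many concave features (cavity, slots,
   holes) outward — so the default stops at 2 pairs, keeping the mesh
   volume within 5% of the occupancy volume. `simplify_mesh()` exposes the
   full chain (face reduction, Laplacian, Taubin) for meshes where the
   conventional settings are appropriate; on closed convex surfaces 50
   Taubin iterations preserve volume within 2% while the same number of
   plain Laplacian passes visibly shrinks them, and the test suite pins
   both behaviours. Adaptive remeshing is not implemented; decimation plus
   Taubin reaches printable quality on all phantoms tried.

```{r pipeline}
library(moldkit)
anatomy <- make_anatomy(phantom_spec(), seed = 7)
build <- build_mold(anatomy$study, mode = "transverse")
mold_qc(build$mold)
export_stl(build$mold$mesh, "mold.stl")
```

## Geometric validation

The original validation compared photographed tissue sections with MRI
contours after mold-guided cutting, via the Dice similarity coefficient
$\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)$. A digital phantom cannot be
photographed, so the geometric analogue implemented here pairs, for every
slot plane, the outline cross-section with the cross-section of the
specimen *as seated in the mold*: bounded below by the carved cavity floor
(the quantity the mold actually controls; over the anchor holes, where the
specimen is unsupported, by its own lower surface) and above by the
specimen's upper surface. On the default phantom at 1 mm spacing and
$\sigma$ = 2 mm, every slot's outline-vs-cavity Dice exceeds 0.99. These
numbers quantify the *design's* registration accuracy only; they are not
comparable to patient DSCs, which fold in segmentation error, tissue
deformation and the manual photo alignment.

`mold_qc()` additionally checks: mesh watertightness and orientation
(every edge shared by exactly two consistently wound faces), the
insertability invariant (no material above any empty voxel in a column —
asserted against a brute-force column scan in the tests), hole centering
(≤ 0.5 voxel), measured hole opening diameter, and interslot spacing
against the requested slice spacing (exact up to half-voxel rounding of
slot row positions).

## The phantom

`make_anatomy()` emulates a nephrectomy specimen analytically: an
ellipsoidal kidney (default semi-axes 50 x 28 x 22 mm), a spherical tumor
(radius 21 mm, optionally lobulated by a random degree-2 spherical-harmonic
perturbation) centered on the kidney surface toward the lower pole so that
its anchor hole clears the hilum's, a hemispherical hilar notch on the
medial surface, and a fat shell whose thickness varies smoothly between 4
and 12 mm with sharp minima of 1 mm over the tumor apex (the tumor contact
point) and 3 mm at the kidney contact point. Every quantity is stored in an
analytic ground-truth record, so validation metrics never re-derive
geometry from the voxelized masks. What the phantom does *not* emulate:
segmentation error, specimen deformation after resection, fat
redistribution, MR intensity artifacts. Green tests therefore demonstrate
the correctness of the geometry pipeline, not clinical accuracy.

## Habitats

Within the tumor, the seven co-registered channels (T1w, T2w, T1 map,
Ktrans, IVIM D0 and f, R2*) are assembled into a per-voxel feature table.
Channels carry incommensurate units (ms, min⁻¹, 10⁻³ mm²/s, ...), so each
is z-scored over the tumor mask before clustering — the clustering outcome
should not depend on unit conventions. Habitats are found by k-means with
k-means++ seeding and 10 restarts (k-means local minima must not leak into
results), labels sorted by size for determinism, and per-habitat profiles
reported as median/IQR on the *raw* channel values.

The number of habitats is selected by mean silhouette over k = 2..6 (ties
toward the smaller k; a maximum below 0.25 raises a "no habitat structure"
flag). The phantom's default habitat layout plants three regions — a
necrotic core (low Ktrans and f, high D0, T1w-hypo/T2w-hyperintense), a
well-perfused rim on the kidney side (highest Ktrans), and an outer rim
with the lowest diffusivity and highest R2* — with adjacent-region means
4 SD apart in every channel, about 5,000 tumor voxels on the 2-mm map
lattice. Under these conditions silhouette selection returns k = 3 in at
least 18 of 20 seeded runs and the labels match ground truth with adjusted
Rand index 1.0.

```{r habitats}
maps <- make_parameter_maps(anatomy, seed = 7)
feats <- build_feature_table(maps$stack)
select_k(feats$features, 2:6, seed = 1)$k     # 3
hm <- cluster_habitats(feats, 3, seed = 1)
habitat_profiles(maps$stack, hm)
```

## Problem sizes and defaults

The default phantom voxelizes to roughly 135 x 101 x 95 at 1 mm; a full
mold build (frame, roll, resampling, carving, meshing, QC) takes well under
a minute on one core, and the complete habitat-recovery study (20 seeds x
select_k over 2..6) a similar time. The compact phantom used by most unit
tests scales the kidney to 30 x 17 x 14 mm. Key defaults, with the reason
they are what they are:

| parameter | default | why |
|---|---|---|
| mold lattice spacing | 1 mm | sub-printer-accuracy, tractable volumes |
| outline smoothing sigma | 2 mm | removes voxel steps without erasing anatomy |
| block margin / base | 10 mm | wall strength around the cavity |
| slot width / bridge | 2 mm / 5 mm | knife clearance / mold integrity |
| hole diameter | 20 mm | palpable through the base |
| slice spacing | 5 mm | typical anatomic MRI slice pitch; set from imaging |
| Taubin (mold mesh) | lambda 0.5, mu −0.53, 2 pairs | see meshing note |
| k-means restarts | 10 | local-minimum insurance |

## Known limitations

* The vertical-shadow cavity bridges concavities of the lower surface; a
  strongly lobulated specimen is held by its convex hull below the
  waterline.
* Roll resolution is a few degrees (flat objective near the optimum).
* Dice on the phantom measures design registration, not the full clinical
  coregistration chain.
* No DICOM ingestion, no inter-sequence registration (maps are assumed
  co-registered), no slicer/G-code output, and no two-part molds.
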