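---
title: "Geometric integrity checking of radiotherapy structure masks"
author: "contourQA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric integrity checking of radiotherapy structure masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourQA)
```

## The problem

Organ-at-risk contours drawn on planning CT are binary voxel masks. Human
and semi-automatic contouring produces a recognisable family of defects:
whole slices skipped along the scan axis, stray voxel islands detached from
the organ body, single slices displaced in-plane ("frame shifts"), and
contours whose overall size or shape is implausible for the organ (an empty
bladder contoured where a full one was required, a femoral shaft contoured
along with the head). Treating a plan against a defective mask risks dose
to unintended tissue, and defective masks poison downstream predictive
modelling. `contourQA` implements two complementary families of checks:

* **contiguity checks**, which interrogate one mask's geometry in
  isolation, and
* **cohort percentile models**, which flag contours whose summary features
  are outliers against a cohort of the same region of interest (ROI).

## Mask representation

A mask lives on a `VoxelGrid`: voxel counts $(X, Y, Z)$ along the
left-right, anterior-posterior and inferior-superior axes, with anisotropic
physical spacing in mm (clinical grids typically have finer in-plane than
through-plane resolution). The grid fixes the linearization: voxel
$(x, y, z)$ (0-based) has linear index $i = zXY + yX + x$, x varying
fastest.

`StructureMask` stores the mask run-length encoded: the strictly
increasing 0-based linear indices where the linearized mask switches
value, read as half-open runs $[t_1, t_2), [t_3, t_4), \dots$. An odd
transition count is rejected. Half-open pairs make run filling unambiguous
and the codec exactly invertible; `rleDecode(rleEncode(m)) == m` is
enforced by property tests over hundreds of random masks.

Voxel triples are recovered from linear indices by

$$z = \lfloor i / (XY) \rfloor,\qquad
  y = \lfloor (i - zXY)/X \rfloor,\qquad
  x = i - zXY - yX,$$

applied to every set voxel (runs are expanded, not just their endpoints).

## Geometric metrics

* **Volume** = set-voxel count × voxel volume (mm³).
* **Extent** per axis = max − min of occupied voxel indices. Because
  "range" admits an off-by-one ambiguity, both the exclusive range
  (max − min) and the inclusive span (range + 1) are reported; physical
  quantities use `range_mm = range_voxels × spacing`.
* **Extent ratios** LR/AP, LR/IS, AP/IS are formed from the mm ranges, not
  voxel counts: on anisotropic grids voxel-count ratios would depend on
  slice thickness rather than anatomy. Degenerate masks (a zero range in
  any direction) get an undefined-ratio marker (`NA`) rather than an
  error, so cohort models can treat them as automatic outliers.
* **Slice-based extent**: iterating over occupied z-slices, the LR and AP
  extents of each slice, summarised by the range of those per-slice
  extents over the contour (`range_of_ranges`). A cylinder of constant
  radius scores ≈ 0 (one voxel-quantization step at most); a contour with
  one displaced or bloated slice scores the size of the disturbance.

All metrics defined on non-empty masks raise a classed error
(`contourQA_empty_mask_error`) on empty input, except volume, which is 0.

## Contiguity

Two checks with deliberately different blind spots:

**Extent (projection) check.** For each axis, collect the distinct
occupied coordinates; the mask passes iff every integer between the axis
minimum and maximum is occupied (unique-coordinate count equals the
inclusive span). The per-axis gap positions are reported. This detects any
fully missing coordinate plane — a missing slice — in ~linear time, but a
projection can be complete even when the structure is split: the fixed
four-voxel set $\{(0,0,0), (1,1,1), (2,3,2), (3,2,3)\}$ occupies every
coordinate $\{0,1,2,3\}$ on every axis yet splits into two components. The
check is implemented as whole-axis coordinate-range completeness (the
conservative reading; per-slice 2D gap hunting would be a different,
stricter detector).

**Region growing.** Starting from the set voxel with the lowest linear
index, repeatedly add every unvisited set voxel within Euclidean distance
$r$ (in voxel-index units, regardless of physical spacing) of any visited
voxel, to a fixed point. The mask is contiguous iff the visited count
equals the voxel count. The default $r = \sqrt 3$ makes the closure exactly
26-connectivity; the radius bands $[1, \sqrt 2)$, $[\sqrt 2, \sqrt 3)$ and
$[\sqrt 3, 2)$ reproduce 6-, 18- and 26-connectivity, which the tests pin
with hand-built voxel-pair fixtures. Numerically the radius enters only as
$d^2 \le r^2 + 10^{-9}$; since squared distances between integer voxels
are integers, the tolerance can never flip a verdict, it only guards
against floating-point representation of $\sqrt 3$ itself.

Implementation notes: the frontier is an explicit queue (clinical masks
reach $10^5$–$10^6$ voxels; call-stack recursion would be unbounded), and
the neighbour search enumerates the precomputed integer offset ball, which
is exactly equivalent to an exhaustive distance comparison — any spatial
index would be an internal optimisation that must not change results. The
verdict is seed-invariant (closures of a symmetric relation partition the
set); the tests verify this exhaustively over all seeds on small random
masks, and the lowest-linear-index seed rule merely makes diagnostics
deterministic.

A brute-force `connectedComponentsOracle` — pairwise-distance BFS with no
spatial shortcut, quadratic and intended for small masks — provides the
independent reference; the suite requires 100% verdict agreement on 500
random masks and cross-checks the oracle itself against a union-find
labelling in the tests.

**Empty masks** get a distinct verdict (`contiguous = NA`): an empty
clinical contour is always reportable, but calling it "noncontiguous"
would conflate two different defects. The QA layer flags it as
`empty_mask`.

## Cohort percentile models

Features per contour: volume, the three mm extents, the three extent
ratios, and the LR/AP slice-extent ranges-of-ranges. Percentiles are
linear interpolation between closest ranks (minimum at rank 0, maximum at
rank $n-1$; `stats::quantile` type 7) — the method is pinned and recorded
in reports because different conventions move thresholds by whole voxels
on small cohorts. Thresholds are recomputed per analysed cohort; all
models refuse cohorts smaller than 8 rows (percentiles are meaningless
below that; the floor is configurable).

* **Bladder emptiness**: flag iff volume < cohort 25th percentile
  (the initial condition) AND any extent ratio falls below the cohort 10th
  or above the 90th percentile (undefined ratios auto-flag). The AND
  combination is the design choice: the volume gate expresses "suspiciously
  small", the ratio gate "suspiciously flat"; either alone over-flags
  normal anatomical variation.
* **Femoral ball/shaft distinction**: a row is `ball_shaft` iff volume >
  cohort 20th percentile AND IS extent > 100 mm AND LR/AP ratio < 1.15.
  The two numeric thresholds are calibration constants fitted once on the
  synthetic cohorts (ball-only phantoms are laterally elongated head+neck
  shapes with IS range ≈ 40 mm and LR/AP ≈ 1.3; adding a shaft of three
  ball diameters raises the IS range past 110 mm and pulls LR/AP to ≈ 1.0)
  and are exposed in `modelConfig()` because real institutional cohorts
  will need their own values. A composite contour capturing only a small
  part of the head fails the volume gate and degrades to `ball_only` — a
  designed-in, documented failure mode of the volume-gated rule.
* **Slice-extent outliers**: flag iff the LR range-of-ranges exceeds its
  cohort 90th percentile AND (configurably OR) the AP one exceeds its own.
  AND is the default because genuine frame shifts displace the whole
  slice, inflating both directions, while single-direction exceedances are
  dominated by normal anatomy (an arched cord inflates one direction
  only). The OR mode is exposed since the choice is a judgement call.

The flags are a pure function of (features, config): shuffling the cohort
permutes but never changes them, and a uniform rescaling of all spacings
moves volume and extent percentiles together while leaving ratio features
untouched, so flag sets are scale-equivariant (tested).

## Synthetic phantoms

No public corpus of labelled defective clinical masks exists, so the
package carries a deterministic phantom generator whose cohorts are the
package's validation bench. The standard conditions are 50 contours per
organ with 10% planted defects, on 64×64×80 grids at 1×1×2 mm
(32×32×120 for spinal cords) — clinically plausible anisotropy at desk
scale, small enough that the whole validation suite runs in minutes.

Shapes: full bladders are spheres; empty bladders flattened low-volume
ellipsoids (semi-axes 20×14×6 mm); femoral balls laterally elongated
ellipsoids (24×18×20 mm); ball+shaft a 16 mm sphere with an abutting
96 mm inferior cylinder; cords 5 mm tubes with smooth sinusoidal lateral
drift (amplitude 1–3 mm, wavelength 120–180 mm); rectums curved 14 mm
tubes; brainstem-like shapes tapered tubes. Every clean phantom is
26-connected with at least one voxel of boundary margin, verified against
the brute-force oracle on coarse renditions.

Cohort jitter is drawn from stated uniform ranges recorded in the manifest
header, with one deliberate exception: **full-bladder size jitter is a
draw over three discrete size classes** (semi-axis 20/24/28 mm) rather
than a continuum. The bladder model flags rows outside strict cohort
percentile bounds; under continuous size jitter the voxel-quantized extent
ratios form a quasi-continuous sample, and a strict 10th/90th-percentile
cut then tautologically labels ~20% of *healthy* rows extreme — not a
defect of the model but of conflating shape variation with shape error.
Drawing sizes from discrete classes keeps clean full bladders identical in
shape up to quantization (heavily tied ratio values), so the percentile
gates bind only on genuinely different shapes. Real cohorts are not
discrete, of course; this is the standard trade-off of a synthetic bench —
it demonstrates that the detector fires on the modelled defect and stays
silent on modelled health, not that clinical false-positive rates will be
zero (the opposite is expected clinically).

Defect injectors return the defective mask, a ground-truth label, and the
set of detectors the construction guarantees will fire:

| kind | construction | expected detectors |
|---|---|---|
| `missing_slices` | delete interior occupied slices | extent, region growing |
| `detached_island` | 2³ island inside the bounding box, ≥ 2 voxels (Euclidean) from the body | region growing only |
| `frame_shift` | displaced duplicate of one slice (see below) | slice-extent model |
| `interior_void` | carve a fully interior cube | none (volume deficit only) |
| `slice_oblong` | dilate one slice in-plane | slice-extent model |

The island is placed at a bounding-box corner so every axis projection
stays complete: it is the constructive witness that the extent check is
strictly weaker than region growing. Boundary-slice deletion is refused
(removing an end slice merely shortens the organ).

**Frame-shift design.** A slice's own extent is translation-invariant, so
displacing a slice *and discarding the original* would be invisible to
slice-based extent. What makes frame shifts detectable in practice is
that the displaced contour coexists with anatomy on that slice — the
injector therefore unions the shifted copy (default 6,6 voxels, bounded by
the tube diameter so the disks still overlap) with the original slice
content. This inflates both in-plane slice extents by the shift magnitude
while both contiguity checks still pass, which is exactly the defect class
the slice-extent model exists for.

All randomness flows from one integer seed through R's Mersenne-Twister
(recorded in the manifest header); identical seeds give byte-identical
manifests, mask files and QA reports.

## The QA layer

`runChecks()` ties everything together: per-row mask loading (corrupt
files become an `unreadable` flag — a QA tool must not die on the data it
polices), per-contour contiguity verdicts, per-ROI-group cohort models,
summary counts, and, when ground-truth labels are present, a per-detector
confusion summary in which "accuracy of detected contours" is precision
(flagged rows that are truly defective) and sensitivity is computed over
the rows each detector is expected to catch. `renderContour()` writes a
three-view maximum-intensity projection scaled to physical mm for visual
review.

## Validation problem sizes

The shipped tests and the acceptance script use: 500 random masks on
grids up to 12³ at densities 0.05–0.6 for the oracle-agreement, codec and
detector-ordering properties; exhaustive seed sweeps on 50 small masks;
and the standard 50-contour cohorts (10% defects) per detector for
planted-defect recovery. On these cohorts region growing achieves
sensitivity 1.0 and precision 1.0 for missing slices and detached
islands, the extent check catches all missing slices and (by
construction) no in-box islands, and the slice-extent and bladder models
flag exactly the planted rows.

## Limitations

* Phantoms are smooth idealised solids: no contour noise, no multi-organ
  context, no realistic intensity data. Passing the bench shows the
  algorithms implement their definitions, not that clinical
  false-positive rates match the bench's.
* The femoral thresholds (100 mm, 1.15) are synthetic-cohort calibration
  constants, not clinical truth.
* Orientation handling is axis-order-only: NIfTI volumes are permuted to
  a canonical LR/AP/IS axis order, but flips and oblique orientations are
  ignored — the checks are invariant to them anyway.
* The brute-force oracle is quadratic and intended for masks of at most a
  few thousand voxels.
* DICOM RT-STRUCT polygon parsing is out of scope; masks arrive as NIfTI
  or RLE-JSON.
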