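---
title: "Methods: simulating a gimbal-gantry ultrasound scanner and its slice search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a gimbal-gantry ultrasound scanner and its slice search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gimbalScan)
```

`gimbalScan` simulates, end to end, a low-cost motorized ultrasound gantry
used for ex vivo optimal tumor-slice selection: a probe rides a stepper-driven
linear rail and a two-servo gimbal (pitch and roll), acquires B-mode slices
at many poses, scores each slice for tumor presence, and moves to the pose
with the highest score.  This vignette documents the models, the parameters
that matter, the numerical choices, and what the simulation does and does
not claim about real scanners.

## Coordinate conventions

World coordinates are millimetres with `x` the rail (travel) axis, `y`
lateral, `z` depth; the probe looks down `+z` and the phantom's top surface
is `z = 0`.  Voxel indices are 0-based; the world position of voxel `idx`
is `origin + idx * spacing`, i.e. coordinates refer to voxel *centers*.

## The digital phantom

`buildPhantom()` generates a tissue block as a voxel grid of echogenicity
in [0, 1] plus an integer ground-truth label grid.  The default footprint
is 160 x 120 mm — the footprint of the commercial breast phantom the
simulation emulates — with embedded tumors of 12--18 mm diameter.  Neither
the block's thickness nor the lesion depths are properties we could take
from the physical phantom's published description, so the depth defaults
to 60 mm and fixtures place lesions at mid-depth; both are explicit,
configurable choices.

Lesions are axis-aligned ellipsoids.  A voxel belongs to lesion *k* exactly
when its center satisfies the ellipsoid inequality — a voxel-center
inclusion rule rather than partial-volume blending, chosen because it is
exact and testable: the label grid can be verified voxel for voxel against
the inequality, and the labeled volume converges to the analytic ellipsoid
volume as spacing shrinks (both are tested).  Overlapping lesions are
rejected rather than silently merged.

A low-amplitude background texture (seeded Gaussian noise, sd 0.05,
smoothed by two passes of a [1, 2, 1]/4 kernel along each axis) is added so
that slices are not piecewise constant.  The texture gives scorers and
renderers non-degenerate backgrounds; it does not claim acoustic realism
(no fat/fibrosis heterogeneity, no directional tissue structure).

## Pose, plane and motor model

A pose is `(x, pitch, roll)`.  The gimbal pivot sits `pivotHeight` mm
(default 10) above the surface at the station's `x`.  The imaging plane is
obtained by rotating the zero-pose plane (normal `+x`, spanning lateral
and depth) first by pitch about the world lateral axis through the pivot,
then by roll about the world travel axis.  A gimbal composition is
order-dependent and the hardware description does not fix it; pitch-then-roll
about fixed world axes is this package's documented convention.  Plane bases
are orthonormal to 1e-12 across the search lattice (tested).

The lateral offset `ly` that appears alongside `lx` in descriptions of such
gantries is frozen at 0 here: the hardware has a single actuated linear
axis (one screw rod), so only `x` is a degree of freedom.

Motor emulation uses the actuator constants of the physical build: a
NEMA-17 stepper (200 steps/revolution) on a TR8x2 trapezoidal screw
(2 mm lead), i.e. a 0.01 mm linear quantum, and servos with 1 degree
resolution.  `poseToMotorCommands()` quantizes linear moves by rounding to
the nearest whole step (open-loop stepper behavior) and emits one
absolute-angle command per changed servo; `applyMotorCommands()` plays a
command stream back, so round trips land within one stepper step and one
servo quantum (tested).  Command streams serialize to a diffable plain-text
log.

## B-mode synthesis

`extractSlice()` resamples the phantom on the imaging plane: echogenicity
by trilinear interpolation, labels by nearest neighbor (a label is an
identity, not an intensity, so it must not be blended).  Pixels sampled
outside the phantom get background echogenicity and label 0 and are flagged
`outOfVolume`; the in/out decision uses the continuous voxel-index
coordinates with a 1e-9 tolerance so that lattice-aligned planes are
classified exactly.  When the plane coincides with a voxel plane and the
pixel spacing matches the voxel spacing, interpolation weights are exactly
0/1 and the extracted slice is bit-identical to the voxel slice (tested).

`renderBMode()` applies a conventional display chain: depth attenuation
`exp(-attenuation * depth)` (default 0.01/mm), multiplicative unit-mean
Rayleigh speckle (the first-order statistic of fully developed speckle;
scale `sqrt(2/pi)` gives unit mean), log compression
`log(1 + g I)/log(1 + g)` with gain g = 50, and scaling to [0, 255].  The
image plane is a 60 x 60 mm rectangle rather than the convex fan of a real
curvilinear probe: the fan changes nothing about the search problem and
complicates masks, so the divergence is accepted and documented.

Each pose's speckle field is seeded by hashing the global seed with the
pose's position on the actuator lattice (0.01 mm, 0.01 degree quanta), so
an image is reproducible regardless of visit order — the property that
makes whole scan searches bit-deterministic.

This is explicitly *not* acoustic simulation: no wave propagation,
shadowing, refraction, elevation focus or coupling effects.  Consequences
for interpretation are discussed under Limitations.

## Scoring and saliency

The role of a trained image classifier is played by a deterministic
surrogate: `analyticScore()` maps the lesion area fraction *a* of the
in-volume pixels through the saturating curve `p = a / (a + a0)`, with
half-saturation `a0 = 0.02` (a slice 2% occupied by lesion scores 0.5).
The surrogate is monotone in the one physically meaningful quantity,
reaches 0 exactly when no lesion pixel is imaged, and keeps the scorer
interface a plain black box (`function(image) -> probability`) so a learned
scorer can be plugged in later.  Under the default 60 x 60 mm plane, a
great-circle section of a 14 mm tumor occupies about 4% of the slice, so
typical detected-slice probabilities sit around 0.65--0.8; the saturation
regime can be moved with `a0` but the package does not tune it per fixture.

`occlusionSaliency()` replaces gradient-based class-activation maps, which
require network internals: a sliding patch is replaced by background (in
both pixels and labels — the surrogate reads labels, a learned scorer reads
pixels, and occlusion must blind both), and each pixel accumulates the
positive score drops of the patches covering it, normalized to [0, 1].
`saliencyToMask()` thresholds at a fraction of the maximum (0.5 by default)
and keeps the largest connected component; `diceIou()` compares masks, with
the convention that two empty masks score (1, 1) so that correctly
predicting absence is not penalized.  Note the largest-component step means
mask validation is meaningful on single-tumor slices; on a slice containing
two tumors the predicted mask can cover only one of them by construction.

## The two-level search

Round 1 scans `nstep` stations spaced `slin0` mm apart.  At each station
the zero-angle slice is scored (`lprob`), then the angular sweep visits all
`(2 s_theta + 1)^2` poses `(alpha * i, alpha * j)` serpentinely: the pitch
index runs forward when the direction indicator `d` is 1 and backward when
`d` is 0, the roll index alternates direction with each pitch row, and `d`
itself alternates with the station index (`d = k mod 2`).  Every move of
the serpentine is one `alpha`-step of one servo — the mechanically cheapest
traversal.  The station keeps the zero-angle pose when `lprob >= aprob`
(ties deliberately favor the mechanically simpler pose) and the sweep's
argmax otherwise.

Refinement is specified only as gradually reducing the step until it falls
below a threshold `epsilon`; the schedule here divides the step by
`refineFactor = 2` each round and re-scans a window of half-width equal to
the previous step centered on the incumbent best `x` — a classic
bisection-style coarse-to-fine scheme.  Because the window always contains
the incumbent, the best-of-round sequence is non-decreasing.  Two further
choices the procedure's description leaves open: angular sweeps are
repeated in refinement rounds (so refined poses compete on equal footing),
and `lprob` is the zero-angle score at the station rather than a carry-over
from the previous round.

Everywhere, ties break to the first-visited pose; the incumbent is updated
only on strict improvement.  Scores are memoized on the actuator lattice,
so a pose revisited in a later round returns the identical score.  With
`slin0 = 32`, `epsilon = 1`, `refineFactor = 2` the step sequence is
exactly 32, 16, 8, 4, 2, 1 (six rounds).

`bruteForceSearch()` is the validation oracle: full enumeration of a pose
lattice with the same per-pose seeding and first-visit tie-break.  The
acceptance suite checks, over 20 phantom seeds, that the two-level search
returns exactly the oracle's pose and score over the union of lattices it
visited, while evaluating several times fewer poses than the
epsilon-resolution exhaustive grid.

Detection is attributed per lesion from the slices' label planes: a
lesion's probability under a scan mode is `a_k / (a_k + a0)` for the
largest in-volume area fraction `a_k` it reached in any slice of that mode.
This is exactly 0 for a lesion no slice imaged, and it avoids crediting a
lesion that contributes one sliver pixel with the score earned by another
lesion in the same slice.  A lesion is "undetected" below the threshold
`tau` (default 0.5 — uncritical here, since the linear-mode failure case is
exactly 0).

## Coverage

A voxel is covered when its center lies within half the slice thickness
(default 2 mm) of an acquired plane and projects inside that plane's image
rectangle.  Tumor coverage is evaluated on the phantom's actual lesion
voxels; the total-coverage map may use a coarser sample grid (4 mm in the
bundled analyses) because testing every phantom voxel against thousands of
planes is unnecessary for a summary fraction.  Angular scanning's pose set
at given stations is a superset of the linear one, so its coverage
dominates linear coverage — tested on every fixture.

## Study fixtures and problem sizes

Three fixtures (`makeFixture()`) define the study conditions, all on the
160 x 120 x 60 mm phantom at 2 mm voxels with 2 mm-pixel slices during
search:

- `single_centered`: one 14 mm tumor at (80, 60, 30) on the central scan
  line; search `slin0 = 32`, `nstep = 5`, `epsilon = 1`, `s_theta = 2`,
  `alpha = 2` (the gantry's native 2-degree resolution), 780 evaluations
  over 6 rounds.
- `two_tumor`: tumor 1 as above, tumor 2 displaced 40 mm laterally —
  outside the 60 mm image slab, so unreachable by zero-angle slices;
  search `slin0 = 10`, `nstep = 15`, `epsilon = 2`, and a wider, coarser
  sweep `alpha = 4`, `s_theta = 5` (roll to +/-20 degrees).  The wider
  sweep is a fixture choice, not a new default: reaching a tumor 40 mm
  off-axis requires about 20 degrees of roll, and covering that range at
  the native 2-degree step would quadruple the sweep to 441 poses per
  station without changing what the layout demonstrates.
- `off_axis_only`: only the displaced tumor, so every zero-angle slice
  scores exactly 0.

These sizes keep the full test suite near a minute on one CPU while leaving
every contract non-trivial (hundreds to thousands of pose evaluations per
search).

## What the simulation shows — and what it cannot

The synthetic phantom emulates the *geometry* of the validation setting:
lesion sizes, the on-axis/off-axis layout, the actuator lattice, and
acquisition from many poses.  Passing tests therefore demonstrate
properties of the *search procedure and its plumbing* — oracle-exact
optimization, serpentine mechanics, refinement convergence, coverage
dominance, determinism — under a scorer that measures ground-truth lesion
area.  They do not demonstrate classifier performance on real tissue,
robustness to acoustic artifacts (shadowing, speckle-correlated texture,
coupling loss), or mechanical error sources (backlash, missed steps):
none of those are modeled.  The probabilities printed by this package are
on the surrogate's scale, not a trained network's, and the two scales
should not be compared numerically.

## Numerical choices, briefly

- Boundary tolerances: 1e-9 in voxel-index units for in-volume tests and
  station bounds; refinement stop compares `step >= epsilon - 1e-12`.
- Stepper quantization rounds to the nearest step; servo targets snap to
  the 1-degree servo resolution at emulation time.
- Memoization keys round poses to 1e-6 mm / 1e-4 degree, far below any
  actuator quantum.
- Seed folding uses an exact-in-doubles 69069 multiplicative fold kept
  below 2^31.
- Degenerate inputs: empty lesion lists, single-station scans, all-zero
  score fields and fully out-of-volume slices are all defined (and tested)
  rather than errors; genuinely inconsistent configurations (step below
  epsilon, sweeps exceeding gimbal bounds, stations beyond the rail,
  overlapping or out-of-extent lesions) fail validation before any
  scanning.
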