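---
title: "Tracking and quantifying single-crystal dissolution in 4D tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and quantifying single-crystal dissolution in 4D tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystrack)
```

## The measurement problem

Time-resolved X-ray microtomography can watch individual soluble crystals
dissolve inside a perfused packed bed: a column of inert, bright spacer
particles immobilizes medium-intensity soluble crystals in a dark flowing
medium, and a 3D gray-value volume is reconstructed every few seconds.
`crystrack` turns such a 4D series into per-crystal dissolution kinetics.
The quantity of interest is the *individual dissolution rate* of crystal
*n*,

$$ I_nDR(t) \;=\; -\,\rho\,\frac{\mathrm{d}V/\mathrm{d}t}{A(t)}
   \quad\left[\mathrm{mg\,cm^{-2}\,min^{-1}}\right], $$

the per-crystal analogue of the intrinsic dissolution rate measured on a
compressed disk: mass lost per unit exposed surface per unit time, with
$\rho$ the crystal density (mg cm⁻³), $V(t)$ the crystal volume (cm³) and
$A(t)$ its surface area (cm²). For a convex body whose surface recedes
uniformly at speed $k$ (normal to itself), $\mathrm{d}V/\mathrm{d}t = -kA$
exactly, so $I_nDR = \rho k$ — the closed form every end-to-end test in
this package checks against.

The pipeline has five stages, each usable on its own:

1. **Segmentation** (`segment_crystals()`): circular field-of-view crop,
   removal of the bright spacer phase by an upper gray cut, and
   minimum-cross-entropy (Li) thresholding of the remainder.
2. **Labeling and morphometry** (`label_components()`,
   `measure_objects()`): connectivity-6 connected components; per-object
   volume, surface area, sphere-equivalent diameter, sphericity, centroid.
3. **Tracking** (`track_crystals()`): nearest-centroid candidate links,
   score-based sequence matching with breakup lineage, and two filtering
   passes that remove non-uniquely identified sequences.
4. **Rate estimation** (`compute_indr()`): quadratic smoothing of $V(t)$
   and $A(t)$, analytic differentiation, evaluation of the rate formula.
5. **Population statistics** (`class_timecourse()`, `spatial_map()`):
   sieve-class means with min–max envelopes, and rates mapped to
   cylindrical cell coordinates $(R, Z)$.

A synthetic phantom generator (`phantom_spec()`, `random_phantom_spec()`)
provides scenes with exact ground truth, so the whole chain is validated
without any proprietary beamline data.

## Segmentation choices

**Order of operations.** The spacer phase is removed first (upper gray
cut), then the Li threshold separates crystals from fluid among the
remaining voxels. Doing it in this order keeps the very bright spacer mode
from dragging the crystal/fluid threshold upward.

**Li threshold.** We use the classic iterative fixed point for the
minimum-cross-entropy criterion: with class means $\mu_0(t), \mu_1(t)$ of
the minimum-shifted grays, iterate
$t' = (\mu_0-\mu_1)/(\log\mu_0 - \log\mu_1)$ until the update is below a
quarter gray level. Two numerical details matter. A tiny guard
($10^{-6}$ of the gray range) protects the logarithm when the lower class
mean is zero, which is exactly what happens on two-level images. And on
integer-valued data the criterion is piecewise constant, so "the"
minimizer is a *partition*, not a point: when the histogram valley contains
empty bins, any threshold inside the gap induces the minimizing partition,
and the tests compare partitions (or criterion values), not raw locations.

**Automatic spacer cut.** `spacer_threshold = "auto"` applies Li twice:
once to split background from particles, once more within the bright
subset to split crystals from spacers. The second split is accepted only
if the two classes are genuinely separated (mean difference of at least
three within-class standard deviations); otherwise no spacer population is
present and the cut is disabled. The same bimodality guard makes a
crystal-free volume segment to an empty mask instead of splitting fluid
noise.

**Object-size floor.** `observe_series()` drops objects below 8 voxels
(about two voxel diameters). Anything smaller is below the resolving power
of the measurement and in practice is threshold speckle; the floor is a
parameter, and `measure_objects()` itself keeps everything.

**Morphological opening** (radius in `segmentation_params()`) is provided
for visual cleanup but is off by default: it erodes small crystals and was
never meant to precede measurement.

## Surface area: the estimator matters

Two estimators are provided, and the choice propagates linearly into the
rate estimates because $A(t)$ sits in the denominator of the rate formula:

* `"faces"` — exposed voxel-face counting, the behaviour of classic 3D
  object counters. On smooth surfaces it converges to **1.5×** the true
  area (axis-aligned faces integrate $|\cos|$ of the surface normal), so
  rates computed from it are biased low by the same factor. It is kept as
  the default because it matches what the field's standard plug-ins
  report, and the bias cancels in *relative* comparisons (time courses,
  class orderings).
* `"coarea"` — the smoothed-gradient (coarea-formula) estimate: the binary
  object is Gaussian-smoothed with $\sigma = 1$ voxel and $\int|\nabla u|$
  is taken over its padded bounding box. On digitized balls of radius
  10–30 voxels this is accurate to ~1% and it is the estimator used
  wherever absolute rates are compared with ground truth. $\sigma = 1$
  voxel is large enough to suppress voxelization anisotropy and small
  enough not to round off real facets of crystals tens of voxels across.

Every observation table records which estimator produced it
(`attr(x, "surface_estimator")`).

"Roundness" is reported as 3D sphericity
$\psi = \pi^{1/3}(6V)^{2/3}/A$, clamped to $(0, 1]$ to absorb
discretization error; with the `"faces"` estimator $\psi$ is biased low by
the same 1.5 factor (a voxel cube measures 0.54 rather than 0.81).

## Tracking

Candidate links are nearest-centroid assignments from each frame to the
next (`link_frames()`), deliberately allowing many-to-one matches: two
objects nearest to the same predecessor encode a candidate breakup.
`match_sequences()` then resolves conflicts per step by minimizing

$$ s_{ij} = w_d\,\frac{\lVert\Delta c_{ij}\rVert}{d_{eq,i}}
          + w_v\,\frac{|\Delta V_{ij}|}{V_i}, $$

assigned greedily in increasing score order with deterministic
tie-breaking (lowest previous label, then lowest next label). The
displacement term is normalized by the predecessor's sphere-equivalent
diameter rather than left in raw voxels: both terms are then dimensionless
and of order one for implausible pairings, which is what lets the volume
term dominate in the classic swap scenario — crystal B landing on crystal
A's former coordinates does not steal A's identity, because inheriting A's
track would cost an $O(1)$ volume-consistency penalty while A's true
continuation costs only a small relative displacement. With raw voxel
distances a few voxels of displacement would outweigh the volume term,
defeating exactly the discrimination the score exists to provide.

**Breakup.** When two or more objects attach to one predecessor, the
mother track is closed and every fragment starts a child track carrying
`mother_id`. An extra object only qualifies as a fragment if it is
physically plausible: no larger than the mother (within the growth
tolerance), no smaller than `min_fragment_fraction` (default 5%) of the
mother, and within `fragment_max_distance` (default 2) mother diameters.
Without these gates, a single speck of segmentation noise adjacent to a
large crystal would repeatedly "break up" its track.

**Filtering passes.** Dissolving crystals cannot grow, so pass 1 truncates
a track at the first step where volume or surface grows by more than
`growth_tolerance` (default 5%, sized to absorb segmentation noise at the
object sizes the phantoms emulate). Pass 2 breaks tracks at improbable
sudden changes: a relative volume drop beyond `jump_volume_fraction`
(default 50%) or a sphericity change beyond `sphericity_jump` (default
0.3) in a single step. Pieces shorter than `min_track_length` are removed
with a logged reason (`rejections()`). Finally only tracks with at least
`min_track_length = 4` observations in consecutive frames are accepted —
four points leave one degree of freedom for a quadratic fit.

Manual visual cross-checking of tracked sequences is replaced by an
automated harness (`evaluate_tracking()`): measured observations are
matched to phantom ground truth by nearest centroid and every
ground-truth identity link is checked for recovery.

## Rate estimation

$V(t)$ and $A(t)$ of each accepted track are each regressed on time (in
minutes) by one least-squares quadratic over the whole observed lifetime —
piecewise or higher-order smoothing is deliberately out of scope, matching
the "smooth function, differentiated analytically" approach. The volume
fit's analytic derivative and the fitted surface (a switch allows raw
per-frame surfaces) enter the rate formula; the minus sign fixes the
convention that dissolution yields positive rates. Times where the fitted
surface is non-positive are flagged invalid rather than propagated.

The density default is crystalline NaCl, $\rho = 2165$ mg cm⁻³; any
material is analyzed by passing its density. Physical units are fixed at
measurement time (volumes cm³, areas cm²) so the rate emerges directly in
mg cm⁻² min⁻¹ — and therefore a wrong `voxel_size` rescales every rate
linearly, as one of the unit tests demonstrates.

One caveat is inherent to quadratic smoothing: for series that plateau,
the fitted derivative can turn weakly positive near the window edges, so
non-negativity of reported rates is a property of dissolving-crystal
trajectories (shrinking-sphere and geometric-decay families are tested),
not an algebraic guarantee for arbitrary monotone data.

## Population statistics

Tracks are classified by their *initial* sphere-equivalent diameter into
sieve classes (defaults S 180–250 μm, M 300–400 μm, L 400–500 μm),
half-open $[\ell, u)$ except the last class, which is closed, so boundary
diameters belong to exactly one class. Class time courses report mean,
minimum and maximum of the individual rates of all crystals alive at each
time — the min–max envelope, not a quantile band, is what the "range of
individual values" means here. `spatial_map()` places each track at its
initial centroid in cylindrical coordinates (radial distance from the cell
axis, depth below the upper boundary, both in voxels) with its
lifetime-averaged rate; time-averaged rather than instantaneous rates are
plotted because a crystal occupies one position but many times.

## The phantom generator

`phantom_spec()` renders post-reconstruction volumes directly: dark fluid,
medium crystals, bright spacer spheres, optional Gaussian gray noise, with
bit-reproducible output for a given spec. Crystals are spheres, octahedra
and pyramids (half-octahedra) — the shapes the real population exhibits —
implemented as axis-aligned $L^1$ balls. Uniform surface recession is the
inward offset of every face plane: the circumradius $a$ shrinks at
$k\sqrt3$ (face planes sit at distance $a/\sqrt3$) and the pyramid base
plane at $k$, so $I_nDR = \rho k$ holds exactly for the continuum body. A
sharp saturation front sweeps the cell top-down at constant speed; a
crystal's clock starts when the front passes its depth, reproducing the
top-dissolves-first behaviour of a perfused bed. Scripted breakups remove
a thin slab through a crystal from a given frame on, producing two
fragments with known lineage.

Default scene parameters are the scaled-down acquisition conditions the
tests emulate throughout: 128³ voxels at 11 μm/voxel (≈1.4 mm window), frames
every 6 s, 8 frames, 20 crystals of 200–300 μm equivalent diameter among
40 spacers of 100–140 μm, gray levels 40/150/250 (fluid/crystal/spacer),
noise SD 5 gray (≈5% of the crystal–fluid contrast), front speed 32
voxels/frame. Recession rates default to 50–110 μm/min, back-computed from
NaCl dissolution rates of order 11–24 mg cm⁻² min⁻¹ (the magnitude such
experiments measure) at crystal density. Random placement is rejection sampling inside the field-of-view
cylinder with exact $L^1$ non-overlap tests between polyhedra — a
statistical stand-in for a real packed bed, not a mechanical packing.

What the phantoms deliberately do **not** emulate: partial-volume
intensity at object boundaries, phase-contrast fringes, reconstruction
artifacts (rings, beam hardening), crystal motion, and local saturation
feedback between neighbouring crystals. Passing the phantom suite
therefore demonstrates correctness of the *measurement chain*, not
robustness to every artifact of a real beamline reconstruction.

## Validation experiments and their design

* **Closed-form rate oracle.** A noise-free digitized sphere of radius 22
  voxels receding at 40 μm/min; the full pipeline must reproduce
  $\rho k$ within 5% at every evaluated time. The window is short enough
  (r shrinks 22→20 voxels) that a quadratic tracks the cubic $V(t)$ to
  well under a percent.
* **Identity recovery.** 50 random 20-crystal phantoms; 100% of
  ground-truth identity links must be recovered. These scenes use
  equivalent diameters 230–300 μm and rates 35–60 μm/min so that every
  crystal stays comfortably above the resolution floor for the whole
  window: identity ground truth is ill-posed for sub-voxel remnants, and
  terminal-stage fragmentation is exercised separately by the filter
  fixtures and breakup phantoms. Five scripted-breakup scenes must
  recover mother–child lineage exactly.
* **Filter rules.** Hand-traced volume/sphericity series exercise both
  passes exactly as specified.
* **Labeling and thresholding oracles.** 200 random 32³ masks against a
  recursive flood fill; Li thresholds against the exhaustive
  cross-entropy scan on bimodal fixtures.
* **Population ordering.** Twelve crystals per scene in three sieve
  classes with prescribed distinct rate means (45–55 / 75–85 / 105–115
  μm/min) at 16 μm/voxel (so large-class crystals fit the 128³ window);
  over 20 seeds the recovered class means must reproduce the prescribed
  ordering. Absolute class means are attenuated by the saturation front
  (crystals spend part of the window waiting for it), which affects all
  classes alike and leaves the ordering intact.

Problem sizes (128³ scenes, 8 frames, tens of seeds) were chosen so the
whole suite runs in minutes on a single CPU while keeping every object
large enough for stable morphometry.

## Known limitations

* The exposed-face surface estimator's 1.5× bias rescales absolute rates;
  use `"coarea"` when absolute values matter, and always report the
  estimator alongside rates.
* Tracks are not stitched across gaps: a crystal lost for one frame
  restarts as a new track (consecutive-frame appearance is required by
  design).
* Whole-lifetime quadratic smoothing underestimates strongly curved
  late-stage kinetics; windowed fits are a natural extension.
* The tracker is frame-local (greedy per step), not a global
  minimum-cost-flow formulation; the phantom studies show this suffices
  for immobilized, well-separated crystals, which is the regime the
  instrument produces.
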