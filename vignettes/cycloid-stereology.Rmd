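---
title: "Cycloid-grid stereology on segmented EM stacks: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycloid-grid stereology on segmented EM stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cycloidSV)
```

# The measurement problem

Corneal stromal nerve bundles approach the epithelium and interact with it
in two morphologically distinct ways: thin bundles that penetrate the
basal lamina through a pore (high surface-to-volume ratio), and swollen
bundles whose axons fuse with basal epithelial cells (low surface-to-volume
ratio). The quantities of interest, measured on serial block-face SEM
stacks of segmented tissue, are

* the surface-to-volume ratio (surface density) of each bundle,
* compartment volumes,
* the diameter of the basal-lamina pore at the interaction site,
* the fraction of bundles containing fusion, and
* two-group statistics over bundles (pooled two-tailed Student's t for
  S/V, Mann-Whitney U for pore size).

SBF-SEM stacks are strongly anisotropic: in-plane pixels of a few
nanometres (default here 10 nm) against a 100 nm step between sections.
Isotropic test lines are therefore not available, and surface estimation
uses the classical *vertical section* design instead.

# Vertical-section estimation with cycloid grids

A cycloid arc with parameter $r_c$, $(x, y) = r_c(\theta - \sin\theta,\,
1 - \cos\theta)$ for $\theta \in [0, 2\pi]$, has length $8 r_c$ and tangent
direction density proportional to $\sin\varphi$, where $\varphi$ is the
angle from the arc's minor axis. Casting such arcs on sections with the
minor axis parallel to a fixed *vertical axis* realizes the sine-weighted
line orientation distribution that makes the surface-density estimator

$$\hat S_V = \frac{2\sum_i I_i}{(l/p)\,\sum_i P_i}$$

design-unbiased, with $I$ the transversal crossings between test lines and
the structure boundary, $P$ the test points inside the structure, and
$l/p$ the line length per point ($l/p = 8 r_c$; one point per full arc at
its arc-length midpoint). Aggregation is always ratio-of-sums: sum the
tallies first, divide once. The grid tile holds two arcs in
point-symmetric arrangement, so the test system is invariant under
rotation by $\pi$, and test-point density is one per $\pi (l/p)^2/16$ of
area.

The sampling protocol mirrors manual practice: for each bundle a section
is drawn uniformly at random among the sections in which the bundle is
visible, the grid's vertical axis is set parallel to the basal lamina
(total-least-squares direction of the lamina trace in that section), the
grid phase is uniform within one tile, and — at interaction sites — a
*restriction line* across the pore endpoints confines counting to the
stromal half-plane (the side away from the epithelium centroid).

Strict unbiasedness of the vertical design requires the section planes to
contain the vertical axis and the rotation about that axis to be
randomized. In a single stack all sections are parallel, so the package's
synthetic cohorts make the design exact by symmetry: bundles are surfaces
of revolution whose axis runs parallel to the lamina (in the section
plane), so rotating the design about the vertical axis leaves the
geometry invariant. For real tissue this symmetry holds only
approximately; that caveat is inherited from the original protocol rather
than silently corrected.

# Counting on rasterized masks

Two numerical choices matter.

**Sub-pixel boundary.** The boundary of the target mask is polygonized at
iso-level 0.5. Applied to the raw 0/1 mask, marching squares returns a
45-degree staircase whose length — and with it the crossing count —
overshoots the true boundary by several percent (measured +5.1% on a
rasterized disc). The indicator is therefore smoothed with a small boxcar
(default 5 x 5 pixels) before contouring; the disc experiment then matches
the theoretical expectation to 0.1%. The same smoothed field defines point
membership (bilinear interpolation > 0.5), so $I$ and $P$ describe one
region. Consequence: structures narrower than about 3 pixels fall below
the counting resolution; at the default 10 nm pixels that is 30 nm, far
below any structure of interest here.

**Tangency tie-break.** Only transversal crossings count: the
segment-intersection test requires strict sign changes on both segments,
so grazing contacts (measure-zero events under the random phase)
contribute zero.

Crossing detection is exact segment-vs-segment intersection between the
grid polylines (97 vertices per arc, uniform in arc length; polyline
length within 0.1% of $8 r_c$) and the contour segments, pruned by a
uniform spatial hash. A dense-sampling oracle (10^4 points per arc along
the same smoothed field) reproduces the counts exactly in the test suite.

# The phantom generator

`generateCohort()` builds two calibrated cohorts emulating segmented
SBF-SEM stacks:

* **penetrating** bundles: capsules (cylinder + hemispherical caps),
  radius calibrated by bisection so the closed-form S/V equals the group
  target (default 3.32 1/um; with shaft length 10 um the radius is
  0.626 um);
* **fusing** bundles: a thin shaft (radius 0.3 um, length 5 um) ending in
  a swollen bulb whose radius is calibrated to the group target (default
  1.39 1/um gives a 2.30 um bulb). Surface and volume of the shaft-bulb
  union are exact solid-union closed forms, verified against a dense
  profile-revolution oracle.

Each scene also carries a basal lamina (80 nm slab normal to the in-image
y axis, so every section shows it as a band), an elliptical pore in the
lamina plane, and an epithelium slab above. The fusing bulb is tangent to
the pore (half-voxel contact), which makes the fusing axon 26-connected to
the epithelium through the pore — the classification criterion — while
perturbing the bundle mask by well under 1%. Pore diameters for *both*
phenotypes come from one lognormal (mean 2 um, CV 0.15), reflecting the
finding that pore size does not differ between groups. Between-bundle
biological variation is a mean-one lognormal factor on the calibrated
radius with configurable CV (0 for recovery checks, 0.1 in power
simulations); the published group sizes are 23 penetrating and 20 fusing
nerves.

Voxelization labels each voxel by the highest-priority structure
containing its centre (pore > lamina > bundles > epithelium), at default
10 x 10 x 100 nm spacing — inside the acquisition ranges of the imaging
protocol (4-15 nm pixels, 100 nm z-step). Voxel-centre membership keeps
rasterization deterministic and makes voxel counting a clean Cavalieri
volume estimator (within 1% of the closed form at spacing r/100).

Two sampling details remove small systematic errors:

* **Sub-lattice jitter.** Every scene is shifted by a uniform random
  sub-voxel offset. With all phantoms at identical lattice alignment, the
  100 nm section lattice truncates the outermost slices of a 1.25-um-thick
  capsule and biases pooled estimates by up to about 3%, with the sign
  depending on the alignment; a uniform random sampling start is the
  standard systematic-sampling remedy and restores design unbiasedness of
  the pooled tallies.
* **Multi-cast semantics.** The original protocol used one random section
  per nerve; that remains the default (`casts = 1`). When `casts = k > 1`
  each cast independently redraws both the section and the grid phase, so
  pooling reduces both counting noise and slice-sampling noise.

What the generator does **not** emulate: grayscale EM appearance (it
produces labels, not images), segmentation error, Schwann cells and
intra-bundle substructure, curvature or branching of bundles, and
animal-level clustering (each phantom is one independent nerve; the
original study had 10 animals per group but reported per-nerve
statistics). Passing recovery tests therefore demonstrates correctness of
the measurement chain on ideal segmentations, not robustness to tracing
error.

# Group summaries and recovery checks

Per-bundle estimates $\hat S_V$ are kept for the group t test, exactly as
per-nerve values were compared originally. For *recovering the group
mean*, however, the package pools tallies across all casts of all bundles
in a group (`groupEstimateSV`): with only 5 casts per bundle a per-bundle
ratio is heavy-tailed — a cast landing on a near-tangential slice of a
capsule contributes a locally honest but extreme ratio (up to ~7 for a
3.32 target), and a mean of 23 such ratios swings by 5-10% across seeds.
The pooled ratio-of-sums is the standard design-based group estimator,
extends the estimator's own aggregation rule across bundles, and is
unbiased with a standard deviation near 2% at the published group sizes
(23 x 5 and 20 x 5 casts, ~90 intersections and ~57 points per
penetrating cast at the default l/p = 1 um).

Statistical operations follow the original analysis: pooled-variance
two-tailed Student's t (Welch available behind a flag), and Mann-Whitney U
with the exact permutation distribution fully enumerated for combined
n <= 20 (valid under ties; two-sided p is the doubled smaller tail capped
at 1) and the tie- and continuity-corrected normal approximation above.
Printed-count reproductions use half-away-from-zero rounding: 9 fusing of
21 bundles gives 42.9%, within 0.1 of the printed (truncated) 42.8%.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lp` | 1 um | test-line length per point; arc scale $r_c = lp/8$, point density $16/(\pi\,lp^2)$ |
| `casts` | 1 (protocol), 5 (recovery) | independent (section, phase) casts per bundle |
| `spacing` | 0.01, 0.01, 0.1 um | voxel size of generated stacks |
| `smooth` | 2 px | boxcar half-width for the sub-pixel boundary |
| `cv` | 0 / 0.1 | between-bundle lognormal radius variation |
| `poreMeanDiameter`, `poreCV` | 2 um, 0.15 | common pore-size distribution |
| `alpha` | 0.05 | significance threshold of the comparison reports |

Calibration (`calibrateRadiusForSV`) bisects the closed-form S/V to
relative 1e-8; S/V is monotone decreasing in the free radius within each
shape family, and unreachable targets raise an error rather than
extrapolating.

# Problem sizes used in validation

The test suite runs the full recovery experiment at the published group
sizes (23 + 20 bundles, 5 casts each, default spacing), a 500-cast pooled
sphere check against $3/r$, 100-replicate power and 2000-replicate
type-I-error simulations for the group tests, and the oracle suite
(profile-revolution areas, brute-force crossing counts, rotating Feret
diameters, exact Mann-Whitney enumeration against an independent exact
reference). These sizes were chosen so each check pins its quantity well
inside the stated tolerance while the whole suite stays comfortably
runnable on a single CPU.

# Known limitations

* The vertical-axis rule ("parallel to the basal lamina") is honored as
  specified; for structures that are not surfaces of revolution about that
  axis the single-orientation design is only approximately unbiased.
* Per-bundle `sv_hat` from one section is noisy by construction; treat it
  as the protocol's measurement, not as a precise per-bundle truth.
* `classifyBundle` works in label space: it detects membrane continuity
  only insofar as the segmentation encodes contact through a pore.
* Pore "maximum dimension" is implemented as the per-section maximum Feret
  diameter maximized over sections; a chord-based reading of the lamina
  gap would differ for strongly oblique pores.
* The tube-with-bulb family rejects geometries where the bulb partially
  engulfs the shaft sideways; supported regimes are bulb-at-the-end and
  bulb-swallows-shaft.
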