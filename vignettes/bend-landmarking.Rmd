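---
title: "Automated landmarking of vascular bends: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated landmarking of vascular bends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bendmark)
```

## The problem

The internal carotid artery (ICA) is a tortuous vessel whose distal curved
portion, the carotid siphon, is a common site of aneurysms and stenosis.
Morphometric studies relate vessel geometry to pathology, but manual bend
classification is operator-dependent and labor-intensive. *Landmarking* is the
automated subdivision of a vessel centerline into bends separated by
interfaces, giving objective, reproducible morphometry. bendmark implements
the two published families of landmarking algorithms for centerline polylines,
together with the preprocessing, discrete differential geometry, synthetic
test-curve generators, and sensitivity machinery needed to use them honestly —
because the central empirical lesson of this line of work is that the
*preprocessing parameters*, more than the algorithms, determine the result.

The package operates on centerlines only: ordered 3D polylines (mm units)
through the lumen center, stored proximal end first. Extracting centerlines
from surface meshes or images is out of scope; any extractor (e.g. a
Voronoi-diagram-based one) can feed its output in as CSV or ASCII XML PolyData.

## Preprocessing

Centerlines inherit non-uniform, noisy sampling from whatever produced them,
while the curvature and torsion estimators need smooth, uniformly sampled
input. Preprocessing has three parameters:

* `r` — resampling spacing (mm). Default **0.1**.
* `lam` — Laplacian smoothing factor. Default **1.2**.
* `n_iter` — smoothing iterations. Default **100**.

These defaults are the parameter set that produced stable, anatomically
plausible results on ICA-scale vessels (~60–70 mm siphons); they are physical
quantities, so `r` must be rethought for vessels at other scales.

**Resampling** interpolates a Catmull–Rom (cardinal, tension 0) spline through
the input points, evaluates it densely (at ~`r`/16), and marches along the
dense polyline emitting a point at every crossing of Euclidean distance `q`
from the previous point, with `q` adjusted in a few passes so the march ends
exactly on the distal endpoint. Uniform *chord* spacing is exactly what the
uniform finite-difference stencils assume, and chord marching stays uniform
even where a noisy curve wiggles below the spacing scale (where uniform
spline-arc placement lets chords contract at spikes). The final segment may
be slightly shorter; it is excluded from the uniformity check, and the end
stencils are one-sided and excluded from peak detection anyway.

**Smoothing** applies `n_iter` sweeps of the umbrella update
`p_i <- p_i + lam * ((p_{i-1} + p_{i+1})/2 - p_i)` to interior points with the
endpoints held fixed. The sweep updates points in place from the proximal end
(Gauss–Seidel style). This is a deliberate numerical choice: a simultaneous
(Jacobi) update of the same stencil is linearly unstable at the grid Nyquist
frequency for `lam > 1` (amplification factor `1 - 2*lam`), whereas the
sequential sweep is stable for `lam` up to 2 — the full range in which the
smoothing factor is practically used. Smoothing shrinks the curve toward its
endpoint chord at a diffusion length of roughly `r * sqrt(lam * n_iter)`
(≈ 1.1 mm at the defaults), which is what suppresses segmentation noise while
preserving ~10 mm anatomical bends. Two side effects matter for testing: an
analytically constant-curvature curve (helix) no longer has constant curvature
near its fixed endpoints after smoothing, and heavy smoothing (`lam > 2`, or
very large `n_iter`) can straighten a vessel until the four-bend subdivision
fails — which the algorithms report as a failure flag, not an error.

The pipeline order is resample → smooth → resample at the same `r`: smoothing
perturbs spacing, and the geometry stencils require it uniform to 5%.

## Discrete differential geometry

With uniform spacing `h`, derivatives are 2nd-order central differences
(one-sided at the ends; the 5-point third-derivative stencil replicates its
nearest interior value at the two end points, which are excluded from peak
detection). Then, per point:

* curvature `kappa = |r' x r''| / |r'|^3` (1/mm, ≥ 0),
* torsion `tau = r''' . (r' x r'') / |r' x r''|^2` (1/mm, signed), set to 0
  where `|r' x r''|^2 < 1e-12` (straight segments, where torsion is
  undefined),
* Frenet frame `T, N, B` with `N` toward the osculating-circle center
  (undefined and flagged where `kappa <= 1e-8`),
* parallel-transport frame `T, E1, E2`: `E1` seeded from the projection of a
  fixed reference direction (global z by default, with automatic fallback if
  it is parallel to the first tangent) and propagated by the double-reflection
  method, the standard minimal-twist discretization.

Both formulas are invariant to parametrization speed, so the small difference
between chordal and true arc length cancels to leading order; on a helix
sampled at 0.1 mm both estimators sit within 0.005% of the closed forms.

The curvature *vector* is computed as `(r' x r'') x r' / |r'|^4` and projected
onto `(E1, E2)` to give the components `k1, k2`. This exact construction —
rather than differencing the unit tangents — makes `k1^2 + k2^2 = kappa^2` an
algebraic identity up to frame orthonormality (~1e-12), and uses only second
derivatives. The direction angle `theta = atan2(k2, k1)`, unwrapped along arc
length and frozen across points with `kappa < 1e-6`, is the curvature-vector
trajectory: within a planar bend it is constant, it steps by ~180° at an
inflection, and on a helix it advances at exactly the torsion rate
(`dtheta/ds = tau`), all of which the test suite checks.

## Peak detection

The landmarking literature speaks of curvature and torsion "peaks" without
defining them. `find_peaks()` uses topographic prominence: an interior local
maximum (plateaus collapse to their midpoint) is accepted if its prominence
reaches `min_prominence_frac` of the signal range. The landmarking algorithms
default to 0.05, which suppresses the saddle-like micro-extrema that fine
resampling creates while keeping the major peaks; the first and last two
points are ineligible (one-sided stencils). Two numerical guards matter:

* signals whose total variation is below `1e-3` of their magnitude are treated
  as constant (no peaks) — the resample/differentiate machinery carries
  `O(1e-4)` relative ripple even on analytically constant profiles, and real
  bends vary by order-1 relative amounts;
* `count_peaks()`, the resolution-sensitivity analysis (peak counts versus
  `r`), defaults to `min_prominence_frac = 0`, i.e. it counts all interior
  extrema. A range-relative threshold would make counts incomparable across
  resolutions, because on noisy centerlines the profile range itself varies by
  orders of magnitude with `r`.

## The two landmarking algorithms

**Geometric bends** (`landmark_piccinelli()`): every curvature peak that has
at least one |torsion| peak strictly proximal and one strictly distal defines
a bend spanning its *nearest* enclosing torsion peaks. Nearest (rather than
outermost) enclosure yields the maximal subdivision consistent with one bend
per curvature peak; when consecutive curvature peaks share (or overlap) an
enclosing interval, the boundary is the curvature minimum between them — the
natural separator, and the rule degrades gracefully in the measure-zero case
where a curvature peak lands exactly on a torsion-peak sample. The bend count
is unbounded and bends are anatomically unlabeled; the method transfers to any
tubular structure, at the cost of sensitivity to resolution and noise.

**Anatomical four-bend subdivision** (`landmark_bogunovic()`): bends are the
curved parts between local curvature minima, and interfaces are found where
the curvature-vector direction rotates by more than a threshold angle.
Candidate segments (one prominent curvature peak each, delimited by the
inter-peak curvature minima) are assigned the direction `theta` at their peak,
and traversed proximal to distal. The angle between adjacent candidate
directions, folded to ≤ 180°, is compared against the threshold sequence
**45°, 60°, 45°, 110°** — ICA-specific values, consumed strictly in order. A
candidate failing the current threshold merges into its predecessor (the
merged segment keeps the direction of its dominant curvature peak; a
peak-representative direction is more noise-stable than pointwise trajectory
turning). With four interfaces found, the bends are labeled inferior,
posterior, anterior, superior from proximal to distal; the superior bend ends
at the first curvature minimum distal to its peak. Everything proximal to the
first interface and distal to that end stays unlandmarked, so at most four
bends are returned irrespective of vessel length; fewer interfaces give a
partial result with a failure flag. Where the traversal direction and the
exact angle measurement were genuinely underdetermined by the published
descriptions, the choices here (proximal→distal traversal, first four
qualifying interfaces, peak-representative angles) are recorded as this
package's interpretation. A generic mode (`labels = NULL`, user thresholds)
returns unlabeled bends for other vessels.

```{r example, eval = FALSE}
sip <- make_siphon(siphon_spec())
res <- landmark_bogunovic(sip$centerline)
tidy(res)     # bend table: label, start/peak/end arc length, length (mm)
glance(res)   # one-row summary
autoplot(res) # curvature/|torsion| profile with shaded bends
```

## Synthetic curves and what they do (not) show

`make_helix()` and `make_planar_wave()` provide closed-form oracles.
`make_siphon()` builds ICA-like test vessels from constant-radius circular
arcs joined by short straight blends, each successive bend plane rotated about
the local tangent; a lead-in and lead-out arc flank the labeled bends so every
designed bend has both a proximal and a distal rotation joint. Arc-and-blend
construction (rather than spline sketching) makes the ground truth exact: bend
boundaries are blend midpoints, curvature peaks are arc midpoints, and the
designed plane rotations are exactly the angle jumps seen by the
parallel-transport frame. Defaults mirror the ICA scale: 65 mm total length,
4 bends with rotations 50°, 70°, 50°, 120° (each exceeding the corresponding
ICA threshold), radii 4–6 mm, 3 mm blends, 0.1 mm spacing; `random_siphon_spec()`
draws 4–8 bends with rotations 25–150° for fuzzing. Because arcs have constant
curvature, the within-arc peak position is only pinned down after smoothing
rounds the plateau into a dome, so peak-recovery tests run the standard
preprocessing and use ~1 mm tolerances.

`add_noise()` models segmentation variability as independent per-point
Gaussian jitter (endpoints fixed, seeded). The noisy study cohort used in the
trend tests fixes `sigma = 0.1` mm on 0.1 mm point spacing — sub-voxel scale
for ~0.25 mm rotational-angiography voxels. Real segmentation error is
spatially correlated rather than independent, real vessels taper and have
non-circular bends, and real centerline extractors have their own bias; the
synthetic tests therefore demonstrate *algorithmic* correctness (parameter
recovery, invariances, trend directions), not clinical validity. Indeed
nothing here guarantees that either algorithm's bends coincide with the
landmarks a neuroradiologist would draw.

One measured caveat, documented rather than hidden: with this noise model, the
mean *geometric* bend count at the default prominence occasionally fails to be
monotone between `r = 0.02` and `r = 0.05` mm (the tallest curvature spikes at
the finest resolution inflate the profile range, hence the prominence
threshold, suppressing borderline bends), while the raw curvature/torsion
peak counts are monotone throughout. The trend test asserts monotonicity as
the scientific claim requires and may fail for some cohort seeds.

## Sensitivity and robustness machinery

`coefficient_of_variation()` is `sd/mean` with the sample (n−1) SD — cohorts
here are small (8–10 models); the population variant is a switch.
`sensitivity_sweep()` varies one of `r`, `lam`, `n_iter` while holding the
others fixed, and reports per-value cohort mean, SD, and CV of a bend metric;
the default grids are `r` ∈ [0.05, 0.15] mm, `lam` ∈ [0.4, 2.0],
`n_iter` ∈ [50, 250], i.e. 0.10 ± 0.05, 1.2 ± 0.8, 150 ± 100. For
cross-algorithm comparison only the four most proximal geometric bends are
comparable to the four anatomical ones. Algorithm failures at a grid cell are
counted per cell, never fatal, and sweeps are bit-reproducible given identical
inputs.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run on synthetic vessels of
~65 mm at 0.02–0.5 mm spacing (~130–3300 points), cohorts of 8–10 models, and
100-curve fuzz batches — sizes chosen so the whole suite completes in a few
minutes on one core while still exercising every code path at ICA scale.
Degenerate inputs are defined errors, not crashes: fewer than 2 points,
non-numeric coordinates, duplicate consecutive points (merged with a warning),
resampling spacing ≥ curve length, spacing non-uniform beyond 5% (error
instructs resampling), smoothing that collapses the curve, an inlet
equidistant from both endpoints (orientation ambiguous). A straight line is a
valid input on which smoothing is an exact fixed point, curvature is ~1e-16,
and both algorithms return empty results (with a failure flag where the
four-bend scheme requires bends).

## Known limitations

* Single unbranched polylines only; no branching trees, surfaces, or lumen
  radius information.
* The ICA thresholds are anatomy-specific; applying the four-bend scheme
  elsewhere requires new thresholds (generic mode) and validation.
* Torsion needs third derivatives and is the noisiest quantity; its peaks are
  detected on |tau|, so chirality of a transition is not used.
* The Catmull–Rom interpolant overshoots at very sharp corners relative to
  the sampling scale; heavily corrupted inputs are usable only because the
  smoothing stage is run before geometry is trusted.
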