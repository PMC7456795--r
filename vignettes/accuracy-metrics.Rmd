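---
title: "Methods: automated SEEG implantation accuracy metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated SEEG implantation accuracy metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegaccuracy)
```

## The measurement model

Everything in this package reduces to exact 3D geometry on objects that
electrode segmentation and surgical planning already provide, all expressed
in one common world space in millimetres:

* a **planned trajectory** is the line through the planned entry point (EP)
  and target point (TP), oriented entry→target;
* an **implanted electrode** is a bolt head, a bolt pivot point (the distal
  end of the guide bolt at the skull) and an ordered list of contact
  centroids, deepest first;
* a **head surface** is a triangle mesh (scalp, outer skull or inner skull)
  in the same space.

The package does *not* register images, segment electrodes from clinical
CT, or assign anatomical regions: it consumes the outputs of those steps.
All inputs are assumed co-registered upstream; the package never re-orients
a volume or mesh.

### Implanted trajectory estimators

Four estimators of the implanted trajectory are provided, named A1–A4 as is
conventional for this family of approaches:

* **A1 (bolt axis)** — the line through the pivot point directed from bolt
  head to pivot. It uses no contacts at all, so it measures where the drill
  and bolt aimed the electrode, not where the (possibly bent) electrode
  went.
* **A2 / A3** — a line fit of the two / three most proximal contacts.
* **A4 (windowed line of best fit)** — a line fit of the contacts from the
  first contact *fully outside* the bolt through every contact within a
  20 mm window (inclusive, Euclidean between contact centroids) of that
  anchor.

All contact-based fits are **total least squares**: the line through the
centroid of the selected contacts whose direction (the principal axis of
the centered cloud, by SVD) minimizes the sum of squared *perpendicular*
distances. Perpendicular residuals are the geometrically meaningful ones
for a trajectory; vertical-residual regression would make the fit depend on
an arbitrary axis choice. The fitted direction is oriented proximal→distal
so that planned-vs-implanted angles are small by construction and never
folded.

"Fully outside the bolt" is operationalized as an axial clearance of
`outside_margin` (default 1.2 mm, about half a typical contact length)
beyond the pivot along the bolt axis; the anchor is the most proximal such
contact. Both the window (default 20 mm) and the margin are arguments of
every function that uses them.

### Entry points, target points and the metric set

The implanted target point is the most distal contact, for every estimator
(A1 and A4 therefore always share target metrics — this is asserted in the
test suite). Entry points are defined by intersecting a trajectory line
with the chosen surface mesh (exact ray–triangle tests over every face) and
keeping the intersection nearest a reference point — the bolt head for
implanted trajectories, the planned EP for planned ones. The reference
disambiguates multi-sheet intersections (ears, contralateral scalp) without
any heuristics about mesh orientation.

Per paired electrode the package reports lateral shift at entry and target
(LE, LT: point-to-planned-line distance), Euclidean errors (EE between the
two on-surface entry points; ET between planned and implanted targets), the
**signed depth error** (the along-axis component of the target
displacement, positive = deeper than planned), the angle between
directions, electrode length (on-surface entry to deepest contact), skull
thickness along the A1 axis (the bone span the drill traverses, not the
surface-normal thickness), and the maximum contact displacement from the
fitted line (an electrode-bending proxy). Because the planned TP lies on
the planned line, `ET² = LT² + depth²` holds exactly and is enforced as a
record invariant, as are `LE ≤ EE` and `LT ≤ ET`. Lateral shift alone is
blind to insertion depth; the signed depth error is reported so that
lateral-shift studies remain comparable with Euclidean-distance studies.

### Pairing

Planned and implanted lists are paired greedily over candidates sorted
lexicographically by (entry distance quantized to `distance_tie_tol`,
angle): this literally encodes the two ordered criteria — closest entry
distance first, smallest angle as tie-break — and is deterministic and
permutation-invariant. The quantization tolerance (default 0.5 mm) defines
when two distances count as "tied" and the angle takes over; candidates
farther than `max_ep_distance` (default 15 mm) are never matched, so gross
mismatches surface as unmatched electrodes rather than nonsense pairs.
When no surface is supplied the implanted entry proxy is the bolt head,
which sits roughly one bolt length proximal of the scalp; `max_ep_distance`
must then exceed the bolt length (the phantom default is 25 mm), which is
why surface-free pairing in the tests uses `bolt_length + 10`.

## Agreement statistics

The statistics module implements the analysis toolkit used to validate
automated pipelines against manual measurements: Box-Cox transformation
(profile-likelihood λ over [−5, 5]; an automatic positivity shift of
−min + ε is applied and recorded when differences are negative, since
method differences routinely straddle zero), the D'Agostino-Pearson K²
omnibus normality test (D'Agostino 1970 skewness and Anscombe-Glynn 1983
kurtosis transformations, χ² with 2 df; n ≥ 20 recommended, warned below),
Bland-Altman agreement (bias μ, limits μ ± 1.96σ, CIs from the classical
large-sample results — bias variance σ²/n, limit variance ≈ 3σ²/n),
Wilcoxon signed-rank (zeros discarded, average ranks for ties, statistic
W = min of the signed rank sums, exact two-sided p by enumeration of all
2ⁿ sign patterns up to n = 15, otherwise normal approximation with tie and
continuity corrections), Mann-Whitney U (exact by enumeration up to a
pooled n of 12 without ties), and Pearson correlation with OLS regression.
All p-values are two-sided; no multiple-testing correction is applied, and
the agreement tables record the number of tests performed so readers can
apply their own.

## The phantom: what it emulates, and what it does not

The phantom module is the package's entire test substrate — it generates
cohorts whose true deviations are known by construction, which is what
makes every pipeline property checkable.

The head is an axis-aligned ellipsoid (scalp semi-axes 95/80/70 mm — an
adult head), with the outer skull 5 mm beneath the scalp and the inner
skull a nominal 8.5 mm beneath that, thinned by a factor of 0.45 inside a
lateral "temporal" sector (a smoothstep-weighted band around the ears).
These bone numbers were chosen so that the cohort's stratified skull
thickness lands in the range reported for temporal (≈4 mm) versus
non-temporal (≈8 mm) bone in implantation audits; the sector also labels
electrodes `temporal` / `non-temporal` so stratified summaries are
exercisable. Electrodes carry 10 contacts at 5 mm spacing behind a 25 mm
bolt; planned depths are uniform in 30–45 mm.

Each implanted electrode derives from its plan by, in order: a tangential
entry shift (the whole trajectory translates; the default 1.3 mm matches
typical mean entry errors), a tilt about the shifted entry point (default
2.2°), a signed depth error along the tilted axis (default magnitude 2 mm),
optional quadratic bending beyond the pivot (off by default), then bolt
placement (pivot at the analytic outer-skull crossing, bolt head one bolt
length proximal) and contact placement with isotropic Gaussian noise
(default σ 0.38 mm, the mean contact-segmentation error reported for
automated SEEG segmentation). With `vary_magnitudes = TRUE` (default) each
electrode draws its magnitude uniformly in 0.25–1.75× the stated value
(mean preserved), giving the spread needed for recovery regressions; with
`FALSE` the stated value is injected exactly, enabling per-electrode
recovery checks (e.g. a pure 2° tilt must be read back as a 2.0° angle).
The generator is a pure function of its seed; the seed is echoed in every
output file header.

What the phantom does **not** emulate: brain shift and CSF-loss
biomechanics, realistic CT noise, beam hardening or metal artefacts,
segmentation failure modes (missed or merged contacts), bolt movement
between implantation and imaging, and non-ellipsoidal anatomy. Passing
tests therefore demonstrate that the *measurement pipeline* is exact and
robust under controlled deviations — not that any upstream segmentation or
registration is accurate on clinical images.

The rasterizer paints the head shells, bolt cylinders (radius 1.5 mm) and
contact spheres (radius 1 mm) into a CT-like volume with documented
intensity bands (`ct_intensity_bands()`). Contacts are deliberately the
brightest band and painted last: contacts proximal of the pivot sit inside
the bolt lumen, and making them the top band keeps a single threshold
sufficient to isolate exactly the contact spheres. Note the 1 mm contact
radius needs voxels of ≈1 mm or finer to guarantee every sphere covers at
least `min_voxels` voxel centers; the round-trip tests rasterize at the
native 0.75 mm.

## Numerical choices

* Ray–triangle intersection uses an ε of 1e-9 on the barycentric bounds;
  duplicate hits (shared edges/vertices) merge within 1e-6 mm. Meshes are
  cleaned of zero-area faces at construction.
* A TLS fit declares "ambiguous direction" when the two leading singular
  values agree to better than 1e-9 relative (isotropic cloud), and
  "degenerate fit" for < 2 distinct points.
* Angles are `acos` of a clamped dot product; near 0° this costs ~1e-6
  degrees of precision (square-root loss), which is why identity-phantom
  checks bound metrics by 1e-6 rather than machine epsilon.
* Isosurface extraction is marching tetrahedra (6 tetrahedra per cube,
  linear edge interpolation, vertices welded at 1e-6 of a voxel), keeping
  the largest connected component. Against an analytic sphere
  distance field the vertex radial error is below one voxel diagonal; on
  rasterized (binary-banded) volumes the interface localization error is
  of the same order.
* Connected components are 26-connected; blob centroids are
  intensity-weighted in world space, which removes the half-voxel
  quantization bias a binary centroid would carry.
* Pairing quantizes distances to 0.5 mm before comparing, making the
  "angle decides ties" rule explicit instead of relying on floating-point
  distance ties that never occur.

## Problem sizes used by the test suite

The suite checks geometric primitives against independent oracles (1D
numerical minimization for point-line distance; unit-sphere grid search
plus Nelder-Mead refinement for TLS directions; closed-form sphere chords
for mesh intersection) on 1000 seeded instances each; identity and
recovery phantoms use 100–150 electrodes; pairing recovery and the
A2-vs-A4 noise-robustness property use 50 seeds of small single-case
cohorts; CT round-trips use 2–3 electrodes at 0.75 mm (contacts) and
1.5 mm (surface) voxels. These sizes keep the full suite under two minutes
on one CPU while leaving each property statistically unambiguous; all of
them scale up by changing the phantom spec.

## Known limitations

* Entry-point metrics inherit the mesh discretization error (chord sagitta
  ≈ 0.05 mm for the subdivision-4 phantom ellipsoids; grazing-incidence
  intersections degrade further, which is why near-tangent trajectories
  are excluded from oracle comparisons).
* The A2/A3 estimators use the most proximal contacts regardless of
  whether those contacts lie inside the bolt; with deep insertions the
  most proximal contacts can sit inside the bolt lumen, which is precisely
  why A4 anchors its window outside the bolt.
* Electrode length is defined as on-surface entry to deepest contact;
  depth comparisons should use the signed depth error, not length.
* `run_compute()` pairs one plan file against one electrode file; cohorts
  spanning multiple implantations (the phantom's multi-case files) should
  be computed per case, as `scripts/acceptance.R` does, since entry points
  from different heads share no common space in reality.
* Wilcoxon zero differences are discarded (the classical treatment); the
  Pratt variant is not implemented.
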