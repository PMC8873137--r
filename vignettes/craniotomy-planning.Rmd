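---
title: "Methods: computational craniotomy planning on triangle meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational craniotomy planning on triangle meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniotome)
```

## Scope and model

`craniotome` is the headless computational core of a craniotomy-training
workflow for intracranial-aneurysm surgery: position the head, draw the
craniotomy contour on the skull, remove the bone patch, judge whether the
opening exposes the target along the intended trajectory, open the Sylvian
fissure by retracting the frontal or temporal lobe, and score the drawn
contour against a reference template. Everything operates on indexed
triangle meshes and 3-D polylines in millimetres, in a right-handed
patient-supine frame (+x left, +y superior, +z anterior). There is no
rendering, no interaction device, and no patient data: a synthetic phantom
supplies all anatomy, so every stage is testable end to end.

## The synthetic phantom

`generate_phantom()` builds a deterministic stand-in for segmented patient
models:

* **Skull** — a thick spherical shell: an outer icosphere (default radius
  85 mm, subdivision 4, 5120 faces) plus an inward-facing inner icosphere
  (thickness 6 mm). Both components are watertight with Euler
  characteristic 2. Real skulls are neither spherical nor two concentric
  tables of constant thickness; the algorithms exercised here are
  geometry-generic, which is why a sphere suffices for testing while
  anatomical fidelity does not transfer.
* **Brain** — two closed hemisphere meshes (radius 75 mm) whose flat faces
  sit either side of a *fissure plane* (point + normal, default gap 2 mm).
  A plane is a deliberate simplification of the curved Sylvian fissure.
* **Vessel** — an open polyline in the fissure gap standing in for the
  middle cerebral artery course: ICA terminus, M1 segment, and a
  post-bifurcation stub. The M1 segment is scaled to exactly `m1_length`
  (default 15 mm, a typical adult value; the segment's length matters
  clinically because it conditions the surgical strategy for MCA
  aneurysms). `place_target()` puts the target — the "small sphere"
  standing in for an aneurysm — at any normalized arc length along it.
* **Landmarks** — optic nerve and pterion as named points. Points, not
  meshes: the workflow only needs them for distances and orientation.
* **Templates** — four closed circles (geodesic radius 25 mm) snapped onto
  the outer skull at 2 locations with 2 line widths (1 and 3 mm),
  mirroring a four-template tracing task. Circles replace hand-drawn
  reference shapes, which do not exist for a synthetic scene.

Optional Gaussian vertex jitter (`jitter_sd`, default 0) exercises
robustness; with the default the phantom is bit-reproducible regardless of
seed. All dimensions are implementer-chosen adult-scale values, not
measurements of any patient.

## Head positioning

`clamp_pose()` models the two-axis head inclination with hard limits:
longitudinal (about the left-right axis) saturates at ±90°, transversal
(about the anterior-posterior axis) at ±30°. The limits are stated as
magnitudes in the requirement they implement; the symmetric per-direction
reading is adopted. Axes are head-fixed (intrinsic), longitudinal applied
first; in world coordinates the composite is `R = R_long %*% R_trans`.
The pivot defaults to the skull centroid, a stand-in for the head clamp,
whose true position is not modelled. `apply_pose()` moves every mesh,
contour and landmark rigidly, so all distances, edge lengths and areas are
preserved (verified to 1e-9 relative error).

## Craniotomy: projection, region growing, excision

`project_contour()` snaps each drawn point to its nearest point on the
skull's outer table (exact point-to-triangle minimization) and connects
consecutive points along the surface by recursive chord subdivision: a
chord splits until its midpoint is within `snap_tol_mm` (default 0.5 mm)
of the surface *and* its endpoints lie in edge-adjacent faces. Every mesh
edge crossed by this dense path becomes a **barrier edge**. When the path
slips exactly through a vertex, the barrier is sealed by routing through
that vertex's one-ring. The contour counts as closed when its endpoints
coincide within the snap tolerance (the same tolerance doubles as the
closure test, since no sharper notion of "closed" is specified by the
task).

Two numerical choices deserve note:

* **Edge barrier, not re-meshing.** The contour claims existing mesh
  edges rather than splitting triangles along the exact curve. Precision
  is face-granular, which is well below the millimetre scale at which
  tracings are scored; exact re-meshing would be an extension.
* **Self-intersection detection** works on the dense surface path: only
  segment pairs lying in the same or edge-adjacent faces can truly cross,
  and pairs closer than 4 snap tolerances of arc are the path's own
  continuity. A crossing is a touch within 1e-6 mm. Exact 3-D chord
  crossings are numerically meaningless, which is why the test is
  surface-local.

`region_grow()` floods the outer-surface face-adjacency graph from the
face containing the seed, never crossing barrier edges. Growth reaching
more than `leak_fraction` (default 50%) of the outer-table area aborts
with a leak error — the signature of a gap in the barrier, e.g. an open
contour. The grown set is independent of which interior face seeds it.
`excise()` removes the region's faces; the result gains exactly one new
boundary loop tracing the barrier cycle. Only the outer table participates
in drawing, growing and excision; on the phantom it is identified by
face-centroid radius above the mean shell radius (a single-sheet mesh,
with radial spread under 2%, counts as all-outer), and arbitrary meshes
can pass explicit labels.

## Exposure

The human workflow judges the opening by looking through a microscope;
`evaluate_exposure()` substitutes a quantitative proxy for that
self-assessment. Rays are cast from stratified-random points on a small
sphere around the target (default radius 2 mm) toward the eye; the
visible fraction is the share not blocked by the occluding mesh
(Möller–Trumbore segment–triangle tests). Sampling is a Fibonacci lattice
with seeded jitter: deterministic for a fixed seed, and removing more
faces can only unblock rays, so enlarging the hole never decreases the
fraction. The report adds the minimal clearance between the eye–target
segment and the hole rim, and the hole area when the excision region is
supplied. Because the sampling pattern is fixed in world axes, the
fraction is invariant under joint rigid motion only up to the binomial
wobble of re-orienting the pattern (observed well under 0.05 at 300
rays); monotonicity and determinism are exact.

One modelling consequence of the shell phantom: a craniotomy removes the
full bone thickness, so the occluder used by the pipeline is the *cut
outer table*. Leaving the intact inner table in place would occlude every
ray and report 0 regardless of the opening. Brain meshes are not
occluders by default, matching the convention that the brain is retracted
before the evaluation look.

## Retraction

`build_system()` discretizes both lobes into a mass-spring system: one
particle per vertex, one Hookean spring per unique mesh edge with rest
length equal to the initial edge length. Particles farther than
`fixation_depth_mm` (default 15 mm) from the fissure plane are fixed,
anchoring each lobe in place of its skull attachment. The lobes share no
springs, so they deform strictly separately.

`step_system()` advances positions with position-Verlet,

```
x' = x + (1 - damping) (x - x_prev) + a dt^2,    a = (F_spring + F_ext)/m
```

with defaults dt = 5 ms, damping = 0.02, stiffness = 1 N/mm, mass = 1 g
per particle. These constants are module defaults chosen for stability
(`dt^2 k/m ≈ 0.025 ≪ 1`), not measured tissue parameters. Non-finite
positions raise an error naming the offending dt/stiffness.

`retract_lobe()` is displacement-controlled: lobe particles within the
spatula's influence radius become moving constraints, ramped linearly to
`amount_mm` over `n_steps` with linear falloff `1 - d/r` from the spatula
point, while the rest of the lobe follows through its springs.
Displacement control matches interface-driven retraction semantics and is
unconditionally stable at the boundary, unlike force control. There is no
self-collision or brain–skull contact handling, and no endorsed threshold
for "too much" retraction — a warning limit is left to the caller.
Verified behaviours: zero amount is a no-op, the untouched lobe and all
fixed particles stay bitwise constant, a free particle reproduces the
Verlet recurrence to 1e-9 mm over 1000 steps, and a hanging two-particle
chain settles within 1% of the Hookean extension F/k.

## Contour metrics

Both precision measures work on arc-length resamplings (default step
0.5 mm) with *exact* point-to-segment distances against the other
polyline, so neither depends on the other contour's sampling density.

* **Surface DSC** = `2 TP / (2 TP + FP + FN)`: a drawn sample within the
  tolerance τ (default 1 mm) of the template polyline is a true positive;
  remaining drawn samples are false positives; template samples beyond τ
  of the drawn polyline are false negatives. The underlying definition of
  TP/FP/FN for curves is not fixed by the tracing protocol this mirrors,
  so the tolerance-based construction is adopted and τ is always reported
  with the value — published tracing scores cannot be matched numerically
  without knowing their τ, only procedurally.
* **Hausdorff distance** `H(A,B) = max(h(A,B), h(B,A))` with `h` the
  max-over-samples of the exact minimal distance to the other polyline.
  Discretization error is bounded by the resampling step and stated in
  the report.

Axioms verified in the suite: symmetry of H, zero iff coincident within
discretization, a triangle-like bound up to one step, DSC in [0, 1],
monotone in τ, and rigid-transform invariance of both metrics. Halving
the step perturbs both metrics by less than the step on smooth contours;
heavily kinked polylines lose more length to corner-cutting, which is the
known limit of uniform resampling.

## Pipeline and reproducibility

`run_pipeline()` chains pose → craniotomy → exposure → retraction →
metrics on a stored scene, materializes every default into the persisted
config, and writes a manifest with parameters, seed and MD5 content
hashes of all artifacts; re-running a config reproduces identical hashes.
The `exec/craniotome` script exposes each stage as a subcommand.

## Problem sizes and test design

The defaults (5120 outer skull faces, ~580 lobe particles, 150–400
integration steps, 400–2000 rays) keep a full workflow run around a
second or two, and the complete test suite under half a minute; oracle
comparisons run on icospheres of subdivision 2–4 and on dozens of random
polyline pairs with a fixed seed. Brute-force oracles (exhaustive
closest-point sampling, independently coded flood fill, explicitly
iterated Verlet recurrence, double-loop max-min distances) are kept free
of the code paths they check.

What passing on the phantom does and does not show: the algorithms are
exact on their contracts (projection, growing, excision, integration,
metrics) for clean, manifold, two-table geometry; the phantom does not
probe segmentation noise, non-manifold meshes, anatomical curvature of
the fissure, or tissue-realistic material parameters, so quantitative
outputs (areas, clearances, displacements) describe the synthetic scene
only.

## Known limitations

* Bone removal is surface excision on the outer table; drilling the
  inner table or sphenoid milling is not modelled (the full-thickness
  reading is applied only when choosing the exposure occluder).
* The fissure is a plane, the templates are circles, and the skull is a
  sphere — fidelity stand-ins, flagged wherever they matter.
* No collision handling in retraction; large amounts can fold the lobe
  through itself.
* Binary STL stores float32, so round trips through it are exact only to
  about 1e-4 mm at skull-scale coordinates; ASCII STL/PLY/OBJ round-trip
  within 1e-6 mm and are the defaults.
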