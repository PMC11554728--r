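---
title: "Modeling endovascular coil deployment with discrete elastic rods"
author: "coildeploy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling endovascular coil deployment with discrete elastic rods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endovascular coiling occludes a cerebral aneurysm by filling its sack with a
thin platinum wire that coils up inside; clot formation on the wire then
shuts the sack off from the bloodstream.  Whether a deployment succeeds
depends on where the coil mass ends up: a well-packed core and neck block
inflow, a poorly packed wall region risks recurrence, and coil migrating
into the parent vessel is a failure.  `coildeploy` simulates the mechanical
deployment of such coils into (synthetic or user-supplied) aneurysm
geometries, and grades the resulting coil distribution with an in silico
analogue of the Raymond-Roy occlusion classification.

## The rod model

A coil is modeled as a Kirchhoff rod: an inextensible, unshearable elastic
filament whose state is its centerline plus the orientation of its cross
sections.  We discretize in the discrete-elastic-rods fashion: the
centerline becomes `N` vertices joined by edges; each edge carries an
orthonormal material frame whose third director is the unit tangent.
Rather than storing full rotation matrices, each edge stores a single angle
`phi` measured against the twist-free Bishop frame, which is obtained by
parallel-transporting a seed director along the curve.

The discrete strain energy has three parts:

* an **axial penalty** `sum_j alpha/2 (|e^j|/|ebar^j| - 1)^2 |ebar^j|`
  standing in for exact inextensibility (real coils carry a
  stretch-resistant filament, so axial extension is not a physical mode
  here, just a constraint to be enforced);
* a **bending** term `sum_i b/(2 lbar_i) |kappa_i - kbar_i|^2` where
  `kappa_i` are the integrated nodal curvatures obtained by projecting the
  curvature binormal
  `(kb)_i = 2 t^{i-1} x t^i / (1 + t^{i-1} . t^i)` onto the averaged
  material directors, and `kbar_i` encodes the imprinted natural shape;
* a **twist** term `sum_i beta/(2 lbar_i) tau_i^2` with
  `tau_i = phi^i - phi^{i-1}` measured against parallel-transported
  frames.

`lbar_i` is the Voronoi length (half the sum of the adjacent rest edge
lengths).  The natural configuration is parametrized by its own Bishop
frame, so its rest twist vanishes identically; natural curvatures are
extracted from the natural centerline with the same discrete operators
used for the current state, which makes the natural shape an exact energy
minimum by construction.

Ends are free ("do nothing"): end nodes and edges simply carry fewer
energy terms, so no extra boundary forces are needed.

### Gradients

Forces are the exact analytic gradient of this energy.  The position
gradient has three contributions: the axial term, the curvature-binormal
derivatives of the bending term, and the variation of the reference twist
under vertex motion (the holonomy of parallel transport), which feeds the
twist term.  The stored frames themselves are data: they are transported
in time, never re-derived from positions, so their only positional
sensitivity is the tilt that keeps them adapted — and that tilt is
orthogonal to every curvature binormal, so it drops out of the bending
gradient.  The whole gradient is certified against central finite
differences of the energy (relative error below 1e-5 on random rods, in
practice around 1e-9); the finite-difference oracle, not any transcribed
formula, is the contract.

### Stiffness constants

The rod does not resolve the stock wire's micro-helix; its effect enters
through the torsion-spring stiffnesses

    b    = E_w D1^4 p_c / (32 (2 + mu_w) D2)
    beta = E_w D1^4 p_c / (64 D2),        p_c = D1 * p

with stock-wire diameter `D1`, coil diameter `D2`, pitch factor `p = 1.1`
and (by default) platinum elastic constants `E_w = 168 GPa`,
`mu_w = 0.38`.  Note `beta/b = (2 + mu_w)/2` identically.  Node masses are
uniform (`M = m I`), one segment's worth of stock-wire mass
(platinum density times wire cross-section times wound wire length per
coil length).

### The axial penalty scale

The penalty weight `alpha` is dimensionless.  Internally it multiplies a
reference stiffness proportional to the stock wire's axial rigidity,
`alpha_abs = alpha * E_w A_wire / 128`.  The divisor was calibrated once,
when the model was assembled, so that `alpha = 0.1` keeps the mean
relative segment stretch of the reference deployment well below 1% (about
0.1% in practice) while keeping the axial stability bound — and hence the
admissible time step — as generous as possible; it has been frozen since.
Doubling `alpha` roughly halves the mean stretch, which is the expected
first-order response of a quadratic penalty.

## Dynamics

Newton's second law for the vertices plus a first-order damped flow for
the edge angles (rotational inertia scales with `D2^2` and is negligible;
the angle damping `eta_phi` merely regularizes the otherwise algebraic
condition `dE/dphi = 0`).  Time stepping is symplectic Euler: velocities
first, from forces evaluated at the current configuration, then positions
with the *new* velocities.  After each step the frames are
parallel-transported in time to the new tangents, the Bishop frame is
re-propagated from the first edge, and the holonomy correction is folded
into `phi`, so the stored frames are exactly the Bishop frame at every
step and the material directors never rotate artificially.

Numerical parameters left unset are derived from the coil itself:

* `dt`: the largest power-of-two fraction of a second below
  `0.5 sqrt(m lbar / alpha_abs)` (the axial mode is the stiffest);
  typically 4-15 microseconds for clinical-sized coils.
* `eta_x`: near-critical damping of the slowest bending mode, taken at a
  wavelength of one imprint loop.
* `eta_phi`: a fixed multiple of `dt` times the angular stiffness scale,
  small enough to act quasi-statically and large enough for stability.

## Insertion boundary conditions

The micro-catheter is a quadratic B-spline through three control points
with an arc-length lookup table and an open tessellated tube that acts as
a rigid obstacle.  Nodes whose pushed arc coordinate is still short of the
catheter tip are *kinematic*: their velocity is the insertion speed along
the local spline tangent and their position is the spline point at their
arc coordinate (membership is tracked by pushed arc length, not geometric
containment, so an escaped node is never recaptured).  Rotational degrees
of freedom are always free — the coil can rotate inside the lubricated
catheter.  The step at which a node exits is recorded; all
inextensibility statistics for an edge start at the release of its later
endpoint.  The insertion speed defaults to 20 mm/s; with near-critical
damping the deployment is quasi-static, and halving or doubling this
speed moves the stretch statistics by far less than their own size.

Deployment is two-phase: during insertion the wall is the neck-cut dome
(the sack separated from the parent artery at the neck plane, capped
watertight), mimicking the balloon-assisted containment of the procedure;
after the last node is released, an additional 10% of the insertion steps
run against the full vessel mesh with the catheter retracted, letting the
coil sag toward the parent artery.  Multiple coils are inserted
sequentially as one chain whose virtual connector edges carry no elastic
terms and are invisible to contact.

## Contact and friction

Collision detection runs in two phases each step.  Coil-coil: an octree
(leaf capacity 8, depth cap 12) over edge centers, rebuilt every step, is
queried for non-adjacent pairs with centers within
`sqrt((lbar/2)^2 + D2^2)`; candidates then get an exact segment-segment
minimum distance, and a pair collides iff that distance is at most `D2`.
Coil-wall: an octree over triangle centers with per-triangle
enclosing-sphere radii; a node within `D2/2` of a triangle is in contact
(penetration `D2/2 - distance`; the collision threshold deliberately uses
one radius for node-to-surface distance, where the coil-coil test uses the
full diameter for centerline-to-centerline distance).  The narrow phase
uses closest-feature distances by default; the projection-only rule (no
contact when the plane projection falls outside the face) is available as
`literal_wall = TRUE`, but a literal reading lets nodes slip through mesh
edges, so robustness wins by default.

Contact forces are penalty springs with dissipation.  Coil-coil pairs use
the unnormalized minimum-distance vector exactly as the model defines it,
with forces distributed to the four incident nodes by the contact point's
barycentric weights — pairwise equal and opposite, so momentum is
conserved by construction.  Wall reactions cancel the wall-normal part of
the node's elastic + coil-coil force and add penalty and damping.
Friction is Coulomb: slip-only between coil segments (zero at vanishing
relative tangential velocity — no stick branch exists in that model, a
documented convention), stick-slip against the wall with
`mu_stick >= mu_slip` and a velocity threshold `v_eps = 1e-3 mm/s`.
The friction coefficients default to 0.4/0.4/0.6 — deliberately high for
rigid walls, standing in for the tangential resistance a compliant wall
would provide.  Contact spring constants default to 20 times the bending
scale `b/lbar^3`, stiff enough that penetrations stay small against `D2`
yet far below the axial stability limit; every contact parameter is
overridable.  The Coulomb cap `|F_friction| <= max(mu) |F_perp|` is
monitored inline at every contact of every step.

## Synthetic geometry

`make_synthetic_aneurysm()` builds a spherical sack of radius `R` cut by
a circular neck (defaults: dome radius 2.5 mm, neck radius 1 mm — the
clinically most frequent "very small" class), with optional smooth seeded
radial bumps for ensemble variety.  The phase-1 dome is capped at the
neck; the full-vessel mesh continues into a short capped parent-vessel
stub below the neck.  It stands in for patient-derived meshes, which can
be supplied as watertight STL/OBJ/PLY files together with a neck plane;
`cut_at_neck()` clips and caps them.  What the synthetic dome does *not*
emulate: lobulated or bifurcation geometries, elliptic necks, vessel
curvature around the ostium, and wall compliance — conclusions drawn from
passing tests on it are about the mechanics and bookkeeping of the
method, not about anatomical realism.

## Occlusion analysis

The deployed centerline is voxelized on a cubic grid (default 70 voxels
per axis over the dome's bounding cube): a voxel is occupied iff its
center lies within `D2/2` of the centerline — the capsule union swept by
the cross-section.  A signed distance field of the dome surface (exact
point-to-triangle distance, sign from angle-weighted pseudonormals,
negative inside) partitions the interior into a **core** and a
**boundary** region of equal volume by bisecting the level value; the
**neck region** is a sphere centered at the neck opening with the neck
radius (the sphere is nowhere standardized, so its definition is explicit,
configurable and reported in the output metadata; its reference volume
only counts the part inside the aneurysm).

Volume fractions are reported both referenced to the aneurysm volume
(`psi_BA`, `psi_CA`, `psi_AA`, `psi_SS`) and as region-local packing
densities (coil volume over region volume).  The classifier operates on
the local packing densities — the thresholds (core 20%, boundary 18%,
sphere 18%, all boundary-inclusive) only make sense region-locally:

| boundary | core | sphere full | sphere empty |
|---|---|---|---|
| full | full | I | II |
| full | empty | IIIa | IIIa |
| empty | full | IIIb | IIIb |
| empty | empty | Fail | Fail |

The "boundary full, core empty" row maps to IIIa for either sphere state,
exactly as printed in the source table.  Ensemble statistics use the
population (1/N) convention pointwise and region-integrated; sweep
confidence bands are normal-approximation `mean +/- 1.96 SE` per bin
(bands are otherwise undefined in the protocol being emulated).

## Numerical choices and degenerate inputs

* Antiparallel consecutive tangents (a 180-degree kink) make the
  curvature binormal and parallel transport singular; they raise an error
  rather than being regularized, since such kinks are outside the model's
  validity.
* Twist angles are wrapped to `(-pi, pi]` — never stated in the model's
  sources, but without it coarse discretizations can accumulate spurious
  whole turns.
* Coincident centerlines in a contact pair (distance numerically zero)
  have no defined collision direction; the pair is skipped for that step.
* The equal-volume bisection runs 60 iterations on the voxelized
  interior; `V_C = V_B` holds to well under 0.5% of `V_A`.
* Energy summation limits: the axial sum runs over all `N-1` edges,
  bending and twist over interior nodes only (the printed form of the
  energy uses `n-2` for all three sums; restricting the axial sum too
  would leave one edge of every rod unconstrained, which is clearly not
  intended).

## Scale of the shipped studies

The reference deployment used by the test suite and the acceptance script
is deliberately desk-scale: one helix coil (`D1` 50 um, `D2` 305 um,
`D3` 2 mm) of ~134 mm length (300 nodes) into the synthetic 2.5 mm dome
at 15% packing density — about 1e6 time steps, a few minutes of CPU.  The
penalty study repeats it at `alpha` in {0.025, 0.05, 0.1, 0.2}; its
printed per-alpha stretch values are geometry-specific, so only the
monotone trend is asserted.  The sweep protocol (uniform sampling, 5 bins,
30+ samples per bin) is implemented in full but exercised in tests with a
deterministic stub and small smoke ensembles; full-scale ensembles are a
matter of CPU budget, not of code paths.

## Known limitations

* Rigid walls; compliance is only mimicked through elevated friction.
* No hemodynamics and no clotting — the classifier grades geometry only.
* Explicit integration: the axial penalty sets the time step, so very
  stiff penalties are expensive by construction.
* The complex-3D natural shape is a documented parametric stand-in
  (precessing loops on the `D3` sphere); fidelity to any particular
  manufacturer's imprint is out of scope.
* Catheter-coil friction inside the tube is neglected (free rotation,
  prescribed translation), as in the model this package implements.
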