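---
title: "Simulating four-flippered underwater flight: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating four-flippered underwater flight: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plesioswim)
```

`plesioswim` simulates a neutrally buoyant, four-flippered swimmer — a
plesiosaur-proportioned body — in a grid-based incompressible fluid, and
searches for periodic flipper strokes that carry it forward in a straight
line. This vignette explains the models, the numerical choices behind them,
and what the package's tests do and do not establish.

## The body

The swimmer is an articulated rigid-body system: one rigid trunk (head,
neck, torso and tail fused, as a sturdy trunk is a prerequisite for purely
limb-driven swimming) plus four flippers, each attached by a
three-degree-of-freedom ball joint at its anatomically placed girdle pivot.
`build_swimmer()` generates the geometry procedurally:

* the trunk is a loft of superellipse cross sections whose half-width and
  half-height profiles follow the proportions of a 3.35 m, moderately
  long-necked plesiosaur (total mass about 275 kg at water density);
* flippers are cambered, high-aspect-ratio hydrofoil plates with rounded
  tips and a posteriorly swept, soft-tissue-extended trailing edge;
* every link is watertight by construction and bilaterally symmetric:
  right-side flippers are exact floating-point mirrors of the left ones.

Exact skeletal cross sections for the reference taxon are not available
as data, so the profiles are calibrated only to the overall published
dimensions and outline reconstructions; what matters downstream is the overall
dimensions, flipper area and aspect ratio, and pivot placement. A
`muscle_bulk_factor` of 1.5 adds 50% more soft-tissue volume around the
limb bases through compact-support bumps, leaving the distal flipper
planform bit-identical — the slim/bulky comparison is then a pure
body-shape experiment.

**Minimum feature thickness.** A regular fluid grid cannot resolve solids
thinner than about one cell. The generator therefore floors thin features
(flipper sections, tail tip) at `min_thickness`, 67 mm at the reference
cell size of 66 mm, and the experiment drivers scale this floor
proportionally when running on coarser grids (e.g. 132 mm at the
half-resolution "desk" grid). Without this, a sub-cell-thin flipper
voxelizes to fractional face coverage everywhere and the fluid leaks
through the blade, destroying thrust.

## The stroke model

Limb motion is decoupled per joint into dorsoventral, anteroposterior and
long-axis rotation (pronation/supination) components. Each component
follows a modified sinusoid described by its minimum, maximum and phase;
all sinusoids share a fixed 0.5 Hz frequency (2 s period). Two
modifications make the space biologically expressive:

* a per-sinusoid *time asymmetry* `a` (0,1): the half-cycle sweeping toward
  the ventral/pronate/posterior extreme takes `(1 - a)` of the period, so
  `a > 0.5` gives a faster power stroke;
* a per-limb-pair *rotation hold*: the rotation signal is held flat for
  `hold/2` seconds at each extreme and the sweeps are compressed into the
  remaining time, allowing the underwater-flight pattern of a fixed blade
  pitch with quick rotation at the stroke turnaround. The published figure
  shows a single flat segment per period, so whether the hold sat at one
  extreme or both is ambiguous; the package splits it equally between the
  two extremes, which reduces to the figure's shape when one plateau is
  short.

Left and right limbs move in synchrony (mirrored through the sagittal
plane); fore and hind pairs are free to differ. The flat encoding is
2 pairs x (9 sinusoid values + 3 asymmetries) + 2 holds = 26 free values;
frequency is not searched.

Joint-range presets (`narrow`, `medium`, `wide`) bound the dorsoventral and
anteroposterior extremes per limb pair. The rotation range (+30 deg
supination to -45 deg pronation) and the neutral poses (forelimb -15 deg
dorsoventral / -16 deg anteroposterior; hindlimb -30 / -27) are common to
all presets. The numeric dorsoventral/anteroposterior endpoints were
published only graphically; the shipped values are back-derived from the
reported achieved ranges and the printed percentage of available range each
optimization used, and live in an editable JSON file
(`inst/extdata/joint_ranges.json`) rather than in code. The "fully
abducted" start pose is taken as maximum dorsal elevation of the active
preset at the neutral anteroposterior angle.

## Articulated dynamics

The equations of motion are written in generalized coordinates: six free
base DOFs (world-frame linear and angular velocity; orientation stored as a
rotation matrix and advanced through the exponential map, so pitch beyond
90 degrees is singularity-free) plus 3 angles per joint, 18 DOFs for the
full swimmer. The mass matrix is assembled from per-link COM Jacobians and
mesh-derived inertia (signed tetrahedron decomposition at 1000 kg/m^3);
Coriolis/centrifugal terms come from exact per-link bias accelerations
(inverse dynamics at zero generalized acceleration). Integration is
semi-implicit Euler at the fluid time step.

Joint actuation uses Stable-PD control: the torque law
`tau = -kp (q + dt qdot - qbar) - kd (qdot - qbardot)` evaluates the
position error at the end of the step, and the damping term is folded into
the mass matrix (`M + dt Kd`), which keeps the controller stable at
`kp dt^2` far above the joint inertia, where explicit PD diverges. Default
gains (`kp` 4000 N m/rad, `kd` 200 N m s/rad per joint DOF) track the
reference stroke to a fraction of a degree in vacuum and a few degrees
against fluid load; both are configuration, as no gain values were
published.

## Fluid and two-way coupling

The fluid is inviscid and incompressible (water's viscosity is negligible
at this scale) on a staggered MAC grid: velocity components on faces,
pressure at cell centers. The reference domain is 6.6 x 5.28 x 3.96 m^3 at
100 x 80 x 60 cells; the `desk`, `coarse` and `mini` configurations keep
the domain and halve/quarter the resolution. Advection is BFECC (two
semi-Lagrangian sweeps estimate the scheme's error, a third advects the
corrected field) with the correction clamped to local sample bounds; RK2
back-traces, trilinear interpolation per face grid, and CFL-based
sub-stepping at `0.9 dx / |u|`. Side and bottom boundaries are
no-penetration walls; the top plane is a free surface with `p = 0`
(implemented with the half-cell ghost coefficient, which makes a resting
hydrostatic column an exact discrete solution).

Coupling is a single variational pressure solve. Each step:

1. fluid and body advance independently (advection + gravity; Stable-PD
   torques + gravity),
2. the body is re-voxelized onto the grid at its tentative pose, and one
   symmetric positive semi-definite linear system is solved for pressure.

Voxelization casts axis-aligned rays through a 3x3x3 sub-grid per cell and
classifies sub-cell centers by intersection parity (rays grazing an edge or
vertex are re-cast with a small deterministic offset), giving fluid volume
fractions in exact multiples of 1/27. From the same sub-grid the package
derives per-face fluid area weights `w_f`; a mixed sub-cell pair counts
half, which makes the weighted interface measure the sub-cell volume
without half-cell dilation bias. The discrete constraint per fluid cell is

```
sum over faces of  s dx^2 [ w_f u_f + (1 - w_f) m . (J qdot + dt Jdot qdot) ] = 0
```

— the fluid-covered part of each face moves with the fluid, the
body-covered part with the body, so a uniformly translating body in a
co-moving fluid is exactly divergence-free. Substituting
`u = u* - dt grad(p)/rho` and the pressure impulse
`qdot+ = qdot* + dt M^-1 E^T p` yields a `w_f`-weighted 7-point Laplacian
plus the low-rank body term `E M^-1 E^T`, where each row of `E` is a
solid-area-weighted face normal mapped through the link Jacobian
(`(1 - w_f) dx^2 J^T m`). The same `E` builds the matrix, the right-hand
side and the generalized pressure force, so action-reaction holds
structurally, and with no body present the system reduces entry-wise to
the plain Poisson projection. The solver is matrix-free preconditioned
conjugate gradient with a modified incomplete-Cholesky MIC(0)
preconditioner on the Laplacian part; the `M^-1` application is an exact
dense solve of the small (18 x 18) mass matrix. Interface normals are the
grid-aligned face normals of the discretization, not mesh normals. The
`Jdot qdot` term is evaluated analytically from the link bias
accelerations (tests cross-check it against finite differences). After the
solve the body's velocities receive the pressure impulse and its positions
are re-integrated; faces majority-covered by the body are overwritten with
the body's local velocity for the next advection.

**Gravity and buoyancy.** By default the solve works with dynamic pressure:
for a fully submerged body, gravity on the fluid and the hydrostatic
pressure gradient cancel identically, and the hydrostatic surface integral
over each closed link is exactly Archimedes' `rho V g` at the link
centroid (the COM, for uniform density). The body therefore feels only the
per-link imbalance `(m - rho V) g` — exactly zero at neutral buoyancy — and
a resting neutrally buoyant body is an exact fixed point of the discrete
scheme rather than drifting at the voxelization error. An `explicit` mode
retains gravity in both phases for validation of the discrete hydrostatic
balance; the two must be switched together.

Fractions below 0.01 are treated as solid; fluid cells left without any
pressure connection are pruned. Cells are attributed to the link that
touched them during voxelization, with a dilation fallback for slivers.

## Quality and optimization

A simulation starts from rest in still water — active limbs fully
abducted so every gait begins with a downstroke — and runs at least two
2-second stroke cycles. Quality is evaluated on the second cycle only (the
first is the start-up transient): `q = d_forward - w_dir * |d_perp|
- w_orient * |dtheta|`, with `d_forward` the COM displacement projected on
the initial heading, `d_perp` both perpendicular components (lateral and
vertical are also reported separately), and `dtheta` the geodesic
orientation change over the cycle. The penalty weights (`w_dir` 1 m/m,
`w_orient` 0.5 m/rad) were not published; they are configuration, and the
package's tests use the deviation metrics directly so conclusions do not
hinge on them.

The optimizer is a standard CMA-ES (weighted recombination, cumulative
step-size adaptation, rank-one plus rank-mu covariance updates) written
against the box of the active preset in normalized coordinates.
Out-of-box samples are redrawn up to ten times and finally clamped with a
quadratic penalty, keeping the covariance update unbiased near bounds.
Fixed seeds give bit-identical runs, and parallel evaluation reduces in
sample order so a multi-worker run equals the serial one. The reference
budget is 31 samples per iteration for about 70 iterations (more than two
thousand coupled simulations); those are the defaults of
`cma_optimize()`. The initial search mean places the sinusoid extremes at
the box quartiles (a mid-amplitude stroke — a zero-amplitude mean would
start the search at a quality plateau), dorsoventral leading with
anteroposterior and rotation a quarter-period behind, symmetric timing, no
hold; initial step size is 0.3 of the box width. Single-pair experiments
(forelimb-only, hindlimb-only) search the active 13 coordinates with the
inactive pair locked at its neutral pose.

## Problem sizes and what the tests show

Test and acceptance runs use deliberately scaled-down configurations,
chosen once as the package's fast tier:

* solver validation (projection, hydrostatics, Archimedes, equilibrium) at
  32^3 to 48^3 cells;
* the straight-swimming symmetry check on the `desk` grid (50 x 40 x 30,
  dt = 25 ms, two cycles);
* the forelimb-versus-hindlimb comparison on the `coarse` grid
  (25 x 20 x 15, dt = 25 ms), with CMA budgets of 6–8 samples for 8–10
  iterations — enough for the optimizer to find thrust-producing strokes of
  both kinds, not to converge them. The `coarse` grid is the smallest at
  which limb placement still differentiates hydrodynamically; on the
  `mini` grid the flippers span single cells and the fore/hind contrast
  washes out.

At these sizes the absolute published speeds are not reproducible: cell
sizes of 26–33 cm on a 3.35 m body resolve the flippers with only one or
two cells of chord, numerical viscosity and voxelization drag are large,
and distances per cycle come out several-fold below the full-scale values.
What the scaled runs do establish is directional and structural: thrust
appears and points forward, bilaterally symmetric strokes swim straight,
forelimbs out-pull hindlimbs, added muscle bulk costs distance, and every
conservation/consistency property of the numerics holds. Reproducing the
absolute speeds requires the `paper` grid (about an hour per simulation on
one core) and the full CMA budget — both plain configuration switches
(`sim_config("paper")`, `cma_optimize()` defaults).

## Known limitations

* The flow is inviscid with a coarse interface: boundary-layer effects,
  and hence skin-friction drag, are absent; form drag is overestimated by
  voxelization ("stair-step" artifacts), partially offset by the sub-grid
  fractions.
* Limbs are rigid; real flippers flex and twist. Modeling that would need
  deformable (finite-element) limbs and an entirely different coupling
  scheme, so it is explicitly out of scope.
* Neck and tail are fused to the trunk; tail propulsion and maneuvering
  are out of scope.
* Neutral buoyancy is uniform; lungs or stomach stones shifting the
  buoyancy distribution are not modeled.
* The free surface is a fixed pressure plane (no waves); the swimmer
  starts deep enough that surface effects are small.
* CMA-ES is a local stochastic search: repeated runs find strokes of
  similar but not identical quality, and no run guarantees the global
  optimum of the 26-dimensional space.
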