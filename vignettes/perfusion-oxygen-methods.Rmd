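---
title: "Models and numerical methods: perfusion, shear and oxygen in spheroid-seeded macroporous hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`perfuscaff` models the biophysical micro-environment of MSC/HUVEC
co-culture spheroids inside a perfused macroporous hydrogel scaffold: the
Stokes-regime perfusion flow through the scaffold stack, the wall shear
stress (WSS) the flow exerts on pore walls and scaffold surfaces, and the
steady dissolved-oxygen landscape set by diffusion, pore-scale convection
and cellular Michaelis-Menten consumption. Because segmented volumes of
real seeded scaffolds are not publicly deposited, the package ships a
synthetic-geometry generator that reproduces the measured summary
statistics of the hydrated gels (porosity, mean pore size, spheroid size
and number per seeding density), so that every downstream solver and
statistic is testable end to end.

# Synthetic scaffold geometry

The simulated bioreactor segment is a parallelepiped spanning, along X, a
pure-fluid band (the circular inner channel of the stacked perforated
discs, straightened), the porous hydrogel slab, and a second fluid band
(the annular outer channel). Y and Z are treated as periodic, Z being the
bioreactor axis along which the flow is driven.

The pore network is synthesised as a level set of a smoothed Gaussian
random field: white noise is filtered with an anisotropic Gaussian kernel
and thresholded at the quantile equal to the target porosity, which makes
the realized porosity exact by construction. The kernel's correlation
length is tuned by bisection until the mean pore size - defined, as in the
imaging analysis, as the cube root of the watershed-separated pore volume -
matches the target (108 um hydrated). Two deliberate choices:

* **Anisotropy along X** (default ratio 5). Freeze-dried gels grow lamellar
  ice crystals along the dominant thermal gradient, leaving elongated,
  well-connected pores. Isotropic level-set fields at 25 % porosity sit
  near their percolation threshold and fail to span a slab hundreds of
  voxels thick; the elongated correlation both reflects the directional
  templating and guarantees an X-percolating pore space, which the flow
  problem requires. Draws that still fail to percolate are retried on
  fresh substreams (ten attempts, then an explicit error).
* **Mean pore size via the measurement chain.** The generator scores its
  own output with the same distance-transform/h-maxima/watershed machinery
  the morphometry module applies to imaging data, so the generator-to-
  measurement round trip is exact by construction rather than approximate.

Spheroids are seeded by drawing centres uniformly over pore voxels
(matching the observed strongly uniform spheroid distribution) and
diameters from a lognormal law (CV 0.25, truncated to 40-200 um) rescaled
so the expected volume matches the per-CSD measured means
(6.0-10.9 x 1e5 um^3). Each spheroid is *molded* to its hosting pore: it
acquires the nearest free pore voxels until its nominal volume is reached,
capped at 2.2x its nominal radius, and never overwrites hydrogel. This
mirrors the imaging observation that aggregates conform to pore contours,
and keeps realized volumes on target despite clipping. A clearance rule
rejects centre candidates whose molding region would touch an existing
spheroid, so labelled objects remain individually resolvable; the
spheroid fusion seen late in culture is deliberately not reproduced in
this day-1 geometry. Segment spheroid counts scale the full-scaffold counts
(773-2384 per condition) by the segment-to-scaffold volume ratio, with the
full scaffold taken as an 8.4 mm outer / 3.5 mm inner annular disc.

What the generator does *not* emulate: real pore-shape distributions
(polygonal freeze-dried cavities), the depth-dependent porosity profile
near the gel surface, hydroxyapatite particles, and the curvature of the
annular scaffold (also neglected in the source imaging-to-simulation
chain). Passing tests on synthetic geometry therefore validate the
solvers and estimators, not instrument-specific segmentation quality on
real OCT stacks.

# Perfusion flow: D3Q19 two-relaxation-time lattice Boltzmann

The culture medium (density 993 kg m^-3, viscosity 1e-3 Pa s at 37 C) is
simulated with a D3Q19 TRT lattice Boltzmann solver. Populations are split
into symmetric and antisymmetric parts relaxed at rates `s1` and `s2`;
`s1` carries the kinematic viscosity through
`s1 = (3 nu dt/dx^2 + 1/2)^-1` (lattice sound speed `cs^2 = 1/3`) and
`s2 = 8(2 - s1)/(8 - s1)`, the magic combination
`(1/s1 - 1/2)(1/s2 - 1/2) = 3/16` that places halfway bounce-back walls
exactly midway between fluid and solid nodes. The time step follows the
compressibility rule `dt = 0.06 dx / vmax` with `vmax = 10 mm/s`, the
Poiseuille centreline estimate in the inner channel at the 10 mL/min
operating point; at `dx = 8 um` this gives `dt = 4.8e-5 s`,
`s1 = 0.3616`, `s2 = 1.7161`. The resulting lattice Mach number is 0.104
by construction of the time-step rule - the solver reports it, and the
Stokes-regime validation (exact parabolic profiles, linear force response)
shows compressibility effects are negligible at this operating point.

Hydrogel and spheroid voxels are impermeable solids (halfway bounce-back).
The boundary plan mirrors the bioreactor segment: a specular (free-slip)
reflection realizes the symmetry plane at X = 0, no-slip at X = X_max, and
periodicity in Y and Z. The flow is driven by a constant body force along
Z, incorporated as an equilibrium-velocity shift `du = F/(rho s2)` with
the hydrodynamic velocity read as `(j + F/2)/rho`; this is the simplest
scheme exact to the order needed for steady Stokes flow, and the
plane-Poiseuille profile is reproduced to machine precision (a known
property of magic-parameter TRT). The body force is tuned so the mean
fluid speed on the symmetry plane matches `vmax`; because the regime is
linear, a secant update with populations rescaled about their weights
converges in one or two outer iterations.

Convergence uses a windowed criterion: the relative L2 change of the
velocity field over a 1000-step window. Desk-scale production runs use a
window tolerance of 1e-3; the slowest cross-section momentum mode of the
segment then leaves a residual transient well below one percent of the
field norm, which is orders of magnitude tighter than any bound checked
against it. Validation cases use 1e-8 to 1e-9. The run is initialised from
the one-dimensional two-channel Poiseuille profile (slab treated as
solid), which removes almost the entire slow transient: pore-scale flow
develops within about a hundred steps.

**Reduced-domain choice.** Production runs keep the *physical* channel
widths (1.75 mm inner, 1.5 mm outer) and slab thickness (2.6 mm) at the
8 um lattice spacing, and shrink the periodic Y/Z cross-section to about
0.26 mm instead. The tuned body force scales as `2 mu vmax / a^2` with
the channel half-width `a`, and the pore-level WSS scales with that force;
shrinking the channels would therefore inflate pore WSS by an order of
magnitude and misrepresent the operating point, while shrinking the
periodic cross-section leaves both the force and the pore-scale stress
statistics intact. Typical problem sizes are 731 x 32 x 32 nodes for the
flow stage and a few hundred thousand nodes for oxygen stages.

# Wall shear stress

The viscous stress tensor is evaluated at every solid-adjacent fluid node
from the second moment of the non-equilibrium populations (pre-collision),
`sigma = -(1 - s1/2) sum_q f_q^neq c_q c_q` (deviatoric part), scaled to
physical units by `rho dx^2/dt^2`. Wall normals on the staircase boundary
are detected locally: the normal is the normalised negative sum of offset
vectors to all solid voxels within a cubic window of radius 3 voxels
(a zero resultant falls back to the nearest solid link). The WSS modulus
is the magnitude of the tangential projection of the traction,
`tau = |sigma.n - (n.sigma.n) n|`. Boundary nodes are tagged pore_wall,
inner/outer periphery (channel bands facing the slab) or bioreactor wall,
and region summaries are unweighted node averages, as appropriate for a
uniform lattice. Against plane Poiseuille the node-level WSS matches the
momentum-balance value `f H/2` to the expected one-half-voxel offset
(2.5 % at 40 lattice widths); normals on a discretized sphere of radius 12
voxels are radial to well under 10 degrees in the median.

# Oxygen transport and consumption: D3Q7 TRT

Dissolved oxygen obeys a convection-diffusion-reaction equation over three
phases - medium (D = 3.3e-9 m^2/s), hydrogel (1.6e-9, measured), spheroid
tissue (3e-10) - with concentration continuity at interfaces (partition
coefficients 1) and a Michaelis-Menten sink in spheroids with the measured
cell densities (3.54e14 m^-3 per type) and kinetic constants
(Vmax 5.4e-17 / 2.4e-17 mol per cell per second, K_M 3.8e-3 / 5e-4
mol m^-3 for MSC / HUVEC). A second particle population on a D3Q7 lattice
is relaxed TRT-wise: the antisymmetric rate is phase-wise,
`s- = (D dt/(ce dx^2) + 1/2)^-1` with scale parameter `ce = 1/4`, and
`s+ = 2 - s-`; this pairing fixes the magic combination at 1/4, which
places anti-bounce-back Dirichlet walls halfway between nodes. The
equilibria are `E_0 = c(1 - 3 ce)` and `E_q = c(ce/2 + (c_q.u)/2)`, with
`u` the pore fluid velocity (zero in gel and spheroids, and identically
zero in static-culture mode).

The stability bound on the time step is read as `dt <= dx/(2 vmax)` - the
advective CFL-type rule that involves the maximal velocity; with
`vmax = 10 mm/s` and `dx = 8 um` this gives `dt = 4e-4 s` and a hydrogel
`s- = 1.8519`. In diffusion-only runs the advective bound is vacuous, so
`dt` is instead capped so the largest lattice diffusivity `D dt/dx^2`
stays at or below 0.2, a standard accuracy ceiling. Boundary
concentration `c0 = 0.21 mol m^-3` (medium equilibrated with air at
37 C) is imposed on both X faces of the slab domain by anti-bounce-back
(`g_in = -g_out + ce c0`); the channels are dropped from the oxygen
domain because convective transport keeps them near `c0`. The sink is
evaluated from the previous step's concentration in semi-implicit
(Patankar) form, `c_new = c/(1 + k(c) dt)` with `k` the concentration-
dependent first-order rate of the Michaelis-Menten law; this reduces to
the explicit update when `k dt << 1` (the printed kinetics) while keeping
the concentration unconditionally non-negative for stiff parameter
sweeps (dense or large spheroids).

Verification rests on three independent oracles: a uniform-Dirichlet
domain relaxes to `c = c0` exactly; a constant-sink slab matches the
closed-form parabola `c0 - R x (L - x)/(2D)` to better than 0.1 %; and a
single spheroid in medium matches a one-dimensional spherically-symmetric
two-region finite-difference solution (Picard-iterated Michaelis-Menten
sink, written independently of the lattice solver) within 5 % of `c0`
pointwise. Steady-state flux accounting (anti-bounce-back link transfers
versus total consumption) balances to numerical precision. Derived
metrics follow the study's definitions: hypoxic fraction as the
percentage of spheroid voxels below `K_M = 3.8e-3 mol m^-3` (uniform cell
density makes voxel and cell fractions identical), the periphery/centre
ratio as mean concentration in the outer 20 % X-bands over the central
20 % band, the per-spheroid drop as `1 - min(c)/max(c)`, and the Thiele
modulus in its standard square-root form
`phi = sqrt((rho_MSC Vmax_MSC + rho_HUVEC Vmax_HUVEC) r^2/(D_sph c0))` -
the source expression prints no radical, but both readings round to the
same value (1.05 vs 1.10) at the printed parameters, so the reported
`phi ~ 1` is insensitive to the choice.

The study's geometry-specific oxygen numbers (2.1-fold periphery/centre
ratio, 0.01-5.40 % hypoxia, up to 98 % intra-spheroid drop) belong to the
real OCT volumes, which are not deposited; the package's acceptance
battery therefore checks the solver's *properties* (maximum principle,
flux balance, oracle agreement, monotonicity of hypoxia in spheroid
radius and cell density, periphery-better-than-centre on any seeded
segment) rather than those unreproducible values.

# Morphometry

The imaging-analysis chain is reimplemented for voxel volumes:
trilinear resampling to isotropic spacing (the OCT stacks are
8 x 8 x 1.45 um); Gaussian smoothing; global thresholding (Otsu on the
smoothed histogram by default, overridable); despeckling by removing pore
components under 27 voxels (sub-resolution at 8 um); object separation by
marker-based watershed on the exact Euclidean distance transform, with
markers from an h-maxima transform of depth 2 voxels (the named algorithm
carries no published parameters; 2 voxels suppresses plateau noise
without merging adjacent pores); and 26/6 complementary connectivity for
objects/background. Pore size is the cube root of pore volume; pores are
classified micro (< 100 um) versus macro (> 100 um). Spheroid morphometry
labels phase-2 components and reports count, mean volume and equivalent
diameter `(6V/pi)^(1/3)`.

# Spatial statistics

Cell positions inside spheroids are recovered from single-channel stacks
by 3-D local maxima detection (plateau ties broken lexicographically)
with greedy suppression at the rendered cell size (15 um MSC, 7 um
HUVEC), one maximum per cell body. Ripley's K for 3-D patterns is
estimated as `K(r) = (1/(lambda n)) sum_i count_w(i, r)` with
`lambda = n/V`, translation edge correction in box windows and an exact
isotropic (spherical-cap) correction in ball windows - the cap fraction
of a sphere of radius `d` centred at distance `rho` from the window
centre has a closed form, so no Monte-Carlo sampling is needed. Pooling
over replicate spheroids uses weights proportional to squared point
counts. Significance against the Poisson reference `4 pi r^3/3` uses
rank-based Monte-Carlo envelopes at matched `n` and window: the k-th
extreme of `m` CSR simulations gives exact two-sided non-coverage
`2k/(m+1)` by exchangeability (defaults 99/2, about 96 %; calibration
tests use 199/5 for an exact 95 % envelope). Above the envelope is
clustered, below is dispersed - a formalisation of reading K curves
against the Poisson line. The synthetic day-7 state (`huvec_core`) draws
80 % of HUVECs uniformly in a half-radius core, which the K machinery
classifies as clustered in essentially every replicate; day-1
(`mixed_uniform`) is uniform in the ball by construction.

# Degenerate inputs, ties and tolerances

Thresholding at a porosity quantile makes all-fluid and all-solid limits
exact; an all-fluid request short-circuits the tuning loop. Watershed
ties are resolved by flooding order (lowest marker label first), maxima
plateau ties lexicographically, so every labelled output is
deterministic. All stage randomness flows from one master seed through
named substreams (`derive_seed`), so stages are individually
reproducible. Lattice solvers abort on non-finite fields and on
concentrations below `-1e-9 c0`; the flow solver refuses geometries with
no fluid, and the K estimator refuses `r` beyond half the shortest box
side or the ball radius, where the corrections lose validity.

# Known limitations

Pore-shape realism is limited to two matched summary statistics plus an
anisotropy motivated by ice templating; no attempt is made to reproduce
freeze-drying physics. The flow stage treats gel and spheroids as rigid
impermeable solids (no poroelasticity, no fluid-structure interaction)
and the planar segment ignores the annular curvature. Oxygen transport is
steady-state only, without cell growth, migration or nutrient
co-limitation feedback. The spatial module analyses each cell type
separately (univariate K), matching the study design; bivariate
cross-type statistics are out of scope.
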