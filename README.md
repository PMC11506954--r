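# perfuscaff

Simulation and image-analysis toolkit for the biophysical
micro-environment of MSC/HUVEC co-culture spheroids inside perfused
macroporous hydrogel scaffolds. It is aimed at tissue-engineering groups
who culture bone-forming spheroids in porous gels under perfusion and want
to quantify, in silico, what their cells experience: the pore-scale wall
shear stress the perfusion flow exerts, and the dissolved-oxygen landscape
set by diffusion through gel and tissue against cellular consumption.

## What it computes

**Synthetic scaffold geometry.** Because segmented OCT volumes of seeded
gels are rarely shared, the package generates voxel geometries matched to
the measured statistics of hydrated freeze-dried gels: porosity
ε ≈ 25 %, mean pore size (cube root of pore volume) ≈ 108 µm, and
spheroids of ~100 µm diameter seeded uniformly at the measured per-CSD
(cell seeding density) volumes and counts. Pore networks are thresholded
anisotropic Gaussian random fields (X-elongated, as directional ice
templating leaves them), tuned so porosity is exact and pore size matches
the watershed morphometry.

**Perfusion flow and WSS.** A D3Q19 two-relaxation-time (TRT) lattice
Boltzmann solver computes steady Stokes-regime flow through the segment
(symmetry plane, no-slip wall, periodic cross-section, body-force driven,
halfway bounce-back on pore walls). The relaxation rates follow

    s1 = (3 ν Δt/Δx² + ½)⁻¹ ,   s2 = 8(2 − s1)/(8 − s1) ,

the "magic" TRT pairing with (1/s1 − ½)(1/s2 − ½) = 3/16, and
Δt = 0.06 Δx/vmax keeps compressibility negligible. The wall shear stress
modulus at each solid-adjacent node is the tangential traction

    τ = | σ·n − (n·σ·n) n | ,

with σ from the non-equilibrium second moment and n detected locally on
the staircase boundary. Region summaries (pore walls, scaffold
peripheries, bioreactor wall) are node averages.

**Oxygen transport.** A D3Q7 TRT solver for the
convection–diffusion–reaction equation spans medium, hydrogel and
spheroid phases, with Michaelis–Menten consumption by both cell types

    r(c) = − ρ_MSC V_MSC c/(c+K_MSC) − ρ_HUV V_HUV c/(c+K_HUV) ,

Dirichlet boundary concentration c₀ = 0.21 mol m⁻³ on the slab faces, and
phase-wise diffusivities (3.3/1.6/0.3 ×10⁻⁹ m² s⁻¹). Derived metrics:
hypoxic cell fraction (c < K_M = 3.8×10⁻³ mol m⁻³), periphery/centre
concentration ratio, per-spheroid oxygen drop, and the Thiele modulus
φ = √(ρV r²/(D c₀)).

**Morphometry and spatial statistics.** The OCT analysis chain (isotropic
resampling, Gaussian filter, threshold, despeckle, distance-transform
watershed, labeling; pore size = cube root of pore volume) and a 3-D
Ripley's-K analysis of cell-type clustering (translation/isotropic edge
corrections, n²-weighted replicate pooling, Monte-Carlo Poisson envelopes)
complete the pipeline.

## Worked example

Generate a seeded segment with physical channel widths, run the flow
solver at the bioreactor operating point, and summarise the WSS:

```r
library(perfuscaff)

spec <- scaffold_spec(segment_length_x = 5.85, width_y = 0.256,
                      height_z = 0.256, channel_inner_width = 1.75,
                      channel_outer_width = 1.5,
                      rng_seed = derive_seed(1, "scaffold"))
vol <- generate_scaffold_segment(spec)
attr(vol, "measured_porosity")       # 0.25    (exact by construction)
attr(vol, "measured_mean_pore_size") # 108 um  (target 108)

vol <- seed_spheroids(vol, seeding_spec("CSD4",
                                        rng_seed = derive_seed(1, "seeding")))$volume

cfg <- build_flow_config(rho = 993, mu = 1e-3, dx = 8e-6, vmax = 10e-3,
                         tol = 1e-3, max_steps = 60000L)
fl <- run_flow(vol, cfg)             # tunes the body force to 6.52 N/m3
wss <- compute_wss(fl, vol)
region_mean_wss(wss)
#>            region  mean_tau_pa  max_tau_pa n_nodes
#> 1       pore_wall 4.106665e-05 0.007973585   28251
#> 2 inner_periphery 1.079332e-02 0.013727537     819
#> 3 outer_periphery 4.850237e-03 0.005484645    1017
#> 4 bioreactor_wall 4.874700e-03 0.004874700    1024
```

The pore-wall mean of 0.04 mPa (and even the channel-facing peripheries at
5–13 mPa) sits far below the ~1 Pa stresses known to stimulate
osteogenic mechanotransduction: spheroids inside the gel are effectively
shear-sheltered, so perfusion benefits must come from transport, not
mechanics. On the oxygen side,

```r
thiele_modulus(kinetics_params(), r_sph = 50e-6)   # 1.047
superficial_velocity(10, 12)                       # 1.474 mm/s
```

a Thiele modulus of ~1 for a 50 µm-radius spheroid means consumption and
diffusive supply are comparable — spheroids this size hover at the edge of
diffusion limitation, and larger or denser aggregates develop hypoxic
cores (`hypoxic_fraction()` makes this monotonicity testable).

The numbered scripts under `analysis/` run the full study: geometry and
morphometry (`01`), flow and WSS (`02`), oxygen metrics (`03`), Ripley's-K
clustering (`04`), writing tables and VTK fields under `results/`.

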