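---
title: "Methods: two-phase chip simulation and digital-assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase chip simulation and digital-assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`droplamp` bundles the two computational halves of designing a
droplet-digital LAMP chip: (i) a two-dimensional incompressible two-phase
flow solver used to compare droplet-generation junctions and the channel
structures around them, and (ii) the Poisson partition statistics that turn
counts of fluorescence-positive droplets into absolute template
concentrations.

## Two-phase flow model

The chip flows are viscous microflows (channel width $W = 50\,\mu m$, mean
velocities of order $10^{-2}\,m\,s^{-1}$, so $Re \sim 10^{-1}$ or less and
gravity is negligible at these scales). Both phases are incompressible
Newtonian fluids:

$$\nabla\cdot u = 0,$$
$$\rho\,\partial_t u + \rho(u\cdot\nabla)u =
  -\nabla p + \nabla\cdot\mu\left(\nabla u + \nabla u^{T}\right) + F,$$

with $F$ the surface-tension body force. The interface is carried by a
conservative level-set field $\phi\in[0,1]$ ($\phi=0$ continuous/oil phase,
$\phi=1$ dispersed/aqueous phase, interface at the $0.5$ contour):

$$\partial_t\phi + u\cdot\nabla\phi =
  \gamma\,\nabla\cdot\!\left(\varepsilon\nabla\phi -
  \phi(1-\phi)\,\hat n\right),\qquad
  \hat n = \frac{\nabla\phi}{|\nabla\phi|},$$

where $\varepsilon$ sets the interface thickness and $\gamma$ the
reinitialization rate. Material properties blend linearly so each pure
phase recovers its own values:

$$\rho = \rho_c + (\rho_d-\rho_c)\,\phi,\qquad
  \mu = \mu_c + (\mu_d-\mu_c)\,\phi.$$

Surface tension uses the continuum-surface-force closure
$F = \sigma\,\kappa\,\nabla\phi$ with $\kappa = -\nabla\cdot\hat n$,
evaluated in balanced-force form on the staggered faces so that a static
droplet supports the Young–Laplace jump ($\Delta p = \sigma/R$ in 2D)
without large parasitic currents. Wall wettability enters through a
contact-angle condition: ghost values of $\phi$ in wall cells are
extrapolated so the interface meets the wall at the angle $\theta$,
measured through the dispersed phase
($\hat n\cdot\hat w = -\cos\theta$ with $\hat w$ the wall normal into the
fluid; $\theta = \pi/2$ reduces to a homogeneous Neumann condition).

### Default fluid pair

| parameter | default | units | meaning |
|---|---|---|---|
| `rho_c` | 1164 | kg m⁻³ | fluorinated-oil (carrier) density |
| `rho_d` | 1000 | kg m⁻³ | aqueous reaction-mix density |
| `mu_c` | 1.12e-2 | Pa s | carrier viscosity |
| `mu_d` | 1.01e-2 | Pa s | dispersed viscosity |
| `sigma` | 5e-3 | N m⁻¹ | interfacial tension (surfactant-laden) |
| `theta` | 3π/4 | rad | contact angle through the dispersed phase |

The dispersed viscosity default is an order of magnitude above pure water;
it represents the surfactant/reagent-laden reaction mix and is
configuration-overridable, as are all entries. A contact angle above
$\pi/2$ (oil-wetting walls) is required for water-in-oil droplet formation
in PDMS channels: with a wetting dispersed phase the aqueous stream sheets
along the walls instead of necking.

### Discretization and solver

* Staggered (MAC) grid: pressure and $\phi$ at cell centres, velocity
  components on faces; geometry rasterized as a stair-step fluid mask with
  tagged `wall` / `inlet` / `outlet` boundary faces. Rasterization requires
  at least 8 cells across the narrowest channel.
* Momentum: explicit first-order upwind convection; the dominant
  $\nabla\cdot\mu\nabla u$ part of the viscous stress is implicit
  (backward Euler, matrix-free conjugate gradients), while the small
  transpose-stress remainder (coefficient $|\mu_c-\mu_d|$) is explicit.
* Projection: incremental pressure-correction. The predictor keeps the old
  pressure gradient; the variable-coefficient Poisson equation for the
  pressure increment is solved by conjugate gradients preconditioned with a
  geometric multigrid V-cycle (2×2 cell agglomeration, Galerkin-summed
  coarse operators over fluid-cell lists, symmetrized red-black
  Gauss–Seidel smoothing). The non-incremental form was measured to leave
  an $O(\Delta t)$ artificial slip layer of width $\sqrt{\nu\,\Delta t}$ at
  walls, visible as a flattened Poiseuille profile; the incremental form
  removes it. Default relative tolerance: $10^{-10}$.
* Level-set transport: flux form (mass-conservative up to boundary fluxes
  and $[0,1]$ clipping) with van-Leer-limited MUSCL face values; the
  compressive/diffusive reinitialization flux is evaluated on interior
  faces only, so walls are no-flux.
* Stabilization defaults: $\varepsilon = h/2$ (half a grid cell, the
  conventional conservative level-set thickness on a uniform mesh) and
  $\gamma$ tracking the running maximum velocity magnitude. A thicker
  interface ($\varepsilon = h$) or a $\gamma$ tied to the inlet mean lets
  upwind transport outrun the reinitialization in the junction, where
  local speeds exceed the inlet mean several-fold, and the dispersed
  thread then smears into an unphysical sub-0.5 haze instead of pinching.
* Time step: adaptive, the minimum of an advective CFL bound
  ($0.25\,h/u_{max}$), the explicit surface-tension bound
  $0.9\sqrt{\bar\rho h^{3}/(2\pi\sigma)}$, a reinitialization bound
  $0.2\,h^{2}/(\gamma\varepsilon)$ and an explicit transpose-stress bound
  $0.2\,\rho_{min} h^{2}/|\mu_c-\mu_d|$.
* Boundary conditions: fully developed (parabolic) inlet profiles with the
  prescribed mean velocity, discretely normalized so the inlet flux is
  exact; no-slip walls; zero reference pressure and zero normal velocity
  gradient at the outlet.
* Determinism: the solver involves no randomness; identical configurations
  reproduce bit-identical trajectories.

### Steady single-phase solves

The buffer (linear vs. serpentine) and collection (spiral, splitting
manifold) comparisons concern steady single-phase fields. At
$Re = \rho u W/\mu \approx 2\times10^{-2}$ inertia is irrelevant, so these
are computed directly from the steady Stokes system, assembled sparse
(momentum + continuity on the same staggered layout) and solved with a
direct sparse LU factorization. This is exact in one solve and avoids
time-stepping entirely.

## Channel geometries

All lengths are in micrometres, origin at the lower-left corner; the
out-of-plane depth (default 50, the mould layer thickness) only converts
planar areas to volumes. Defaults not dictated by the chip design were
fixed once at desk-scale values:

* junction feed arms: 4 channel widths (enough for developed inflow);
  outlet channel: 6 widths;
* T-junction step: a one-sided constriction of the dispersed-channel mouth
  to width $W_d - h$ over an axial extent $W_d$ (so `h = 35` on a 50 um
  channel leaves a 15 um mouth);
* serpentine: 4 turns, 400 um limbs, 150 um pitch; spiral: 3 loops,
  250 um pitch, inner radius 200 um; splitting manifold: symmetric
  bifurcation cascade with outlet spacing and stem length of 4 widths.

## Droplet metrics

Droplets are 8-connected components of $\{\phi > 0.5\}$ not attached to the
dispersed inlet. Planar area uses cell counting weighted by $\phi$ with a
one-cell skirt correction; volume is area × depth, and the effective
diameter is that of the volume-equivalent sphere,
$d_{eff} = 2\,(3V/4\pi)^{1/3}$. Detachments are found by tracking free
components across recorded frames (nearest-centroid matching); the
generation frequency is $(n-1)/(t_n-t_1)$ over the last 60% of the run
(the first 40% is discarded as start-up transient), and the summary
diameter is volume-weighted, which makes it robust to satellite fragments
a few cells in size. Pressure probes sit one channel width upstream of the
junction mouth in each feed channel; the two-phase pressure difference is
$P_c - P_d$.

In sweeps, the dispersed feed channel is pre-filled with dispersed phase up
to just upstream of the junction, which removes the uninformative
inlet-transit transient; the run proper still starts from rest with the
junction and outlet full of carrier fluid.

Two measurement subtleties in the structure comparisons are worth making
explicit. First, at equal inlet flux and equal width the *developed*
outlet-centre speeds of the linear and serpentine channels are identical by
construction (same parabola), so the serpentine's buffering is quantified
by the mean speed along the channel centreline: in every 180° turn the
velocity maximum leaves the centreline, making the serpentine's
centre-of-structure speed distinctly lower. Both metrics are reported.
Second, the step-height study compares the junction pressure differential
on magnitude: upstream of a strong mouth constriction the dispersed feed
pressure exceeds the continuous one, so the signed mean $P_c-P_d$ flips
sign while its magnitude — the quantity that grows sharply with step
height and drives breakup — increases by two orders of magnitude between
$h=5$ and $h=40$ µm.

## Synthetic digital-assay model

Each droplet is an independent reactor; template copies per droplet are
i.i.d. Poisson with mean $\lambda = c\,V$ ($c$ input concentration in
copies/µL, $V$ droplet volume in µL). The default volume is
$5\times10^{-4}\,\mu L$ (0.5 nL), the value implied by partitioning a
10 µL reaction into $2\times10^{4}$ droplets; a 0.5 nL sphere has
$d_{eff} \approx 98\,\mu m$, consistent with the simulated generation
scale. Amplification is assumed perfect (a droplet is positive iff it
holds ≥ 1 copy); an optional false-negative rate is exposed for
sensitivity analysis and defaults to 0.

Quantification inverts the positive fraction
$\hat\lambda = -\ln(1-\hat p)$, $\hat c = \hat\lambda/V$, with a
delta-method interval on $\log\hat\lambda$
($se(\hat\lambda) = \sqrt{\hat p/(n(1-\hat p))}$). Dilution-series
calibration fits ordinary least squares of $\log_{10}\hat c$ on
$\log_{10}c$ — the log scale is the natural choice for a series spanning
three decades. Detection curves score a replicate as detected when it
yields at least $k_{min}$ positives (default 3, the smallest count clearly
distinguishable from a clean no-template control); the limit of detection
is the smallest grid concentration detected with probability ≥ 0.95.
Note the Poisson model makes detection at these droplet counts almost
deterministic well below $10^{2}$ copies/µL; a practical LOD at that level
reflects assay chemistry, which this model deliberately does not include.

## What the synthetic tests do and do not show

The generator and solver emulate the *statistical structure* (Poisson
partitioning, monodisperse volumes) and the *hydrodynamic mechanisms*
(shear-driven necking, squeezing, buffering, symmetric splitting) of the
real chip. They do not emulate: three-dimensional pinch-off (the planar 2D
model has no Rayleigh–Plateau instability, so absolute droplet sizes and
frequencies are systematically shifted relative to a real chip even where
their trends with flow ratio and step height are right), fluorescence
readout and image analysis, LAMP kinetics, or surfactant transport
(surfactant enters only through the constant $\sigma$). Passing tests
therefore validate trends, orderings and conservation properties, not
absolute agreement with bench measurements.

## Problem sizes in the shipped test-suite

The packaged tests run the junction campaigns on a 5 µm grid (10 cells
across a 50 µm channel) with `t_end` of 0.06–0.1 s per case, the analytic
benchmarks (Poiseuille, Young–Laplace, transport oracles) on 2.5–5 µm
grids, and the steady comparisons at 5 µm (50 µm channels) or 10 µm
(100 µm collection channels). These sizes were chosen as the coarsest
grids on which the respective phenomena are resolved (≥ 8 cells across a
channel, ≥ 20 cells per droplet radius in the Laplace benchmark). The
production default for design work is 2.5 µm.

## Known limitations

* 2D planar model; depth enters only as a multiplicative volume factor.
* First-order upwind momentum convection (acceptable at these Reynolds
  numbers) and a stair-step representation of curved walls.
* The conservative level set cannot represent films or threads thinner
  than ~3 cells; sub-grid satellites near that floor are filtered by a
  minimum-area threshold (4 cells) in droplet tracking.
* Contact-angle enforcement is first-order accurate and acts only through
  wall-adjacent ghost values; measured wall angles converge slowly, within
  roughly 10–15 degrees on 64² benchmark grids.
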