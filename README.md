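# droplamp

Design tools for droplet-microfluidic digital-LAMP chips, in two connected
halves:

1. **Two-phase chip flow simulation.** A 2D incompressible Navier–Stokes
   solver (staggered grid, Chorin-type incremental projection) coupled to a
   conservative level-set interface model

   &nbsp;&nbsp;&nbsp;&nbsp;∂φ/∂t + u·∇φ = γ ∇·(ε∇φ − φ(1−φ) n̂),&nbsp;&nbsp;
   ρ = ρ_c + (ρ_d−ρ_c)φ,&nbsp;&nbsp; μ = μ_c + (μ_d−μ_c)φ,

   with continuum-surface-force surface tension (F = σκ∇φ) and wall
   contact angles. Constructors are provided for the standard chip
   structures — flow-focusing cross, T-junction (with an optional
   step-constricted mouth), linear and serpentine buffer channels, spiral
   and splitting collection paths — plus droplet detection, the
   volume-equivalent effective diameter d_eff = 2·(3V/4π)^(1/3),
   generation frequency, pressure probes and velocity profiles, and
   scripted design sweeps (droplet size/frequency vs. flow-rate ratio
   u_c/u_d, junction comparison, step-height optimization, buffer and
   collection-path studies). Steady single-phase comparisons use a direct
   sparse Stokes solve (Re ≈ 0.02 in these channels).

2. **Digital-assay statistics.** Poisson partitioning of template into
   monodisperse droplets (copies ~ Poisson(λ = c·V)), positive counting,
   concentration estimation by inversion λ̂ = −ln(1−p̂) with a delta-method
   interval, log10–log10 serial-dilution calibration, and
   detection-probability / limit-of-detection curves.

Intended for microfluidics researchers iterating chip geometry in
simulation before fabrication, and for anyone quantifying droplet digital
assays.

## Worked example: dilution-series calibration

```r
library(droplamp)

d <- run_dilution_series(c(10, 1e2, 1e3, 2e3, 1e4),
                         v_droplet = 5e-4,   # uL (0.5 nL droplets)
                         n_droplets = 2e4, seed = 1)
d$fit
#> Dilution-series calibration (log10 scale, 5 points)
#>   Y = 1.0031 X -0.0139   (R^2 = 0.99976)
```

Each of the five inputs is partitioned into 2×10⁴ droplets; positives are
droplets that received at least one template copy; the detected
concentration is the Poisson inversion of the positive fraction. A slope
near 1 and intercept near 0 on the log10 scale mean the digital readout
recovers input concentrations essentially unbiased across three decades;
R² close to 1 reflects the small counting noise at these droplet numbers.

## Worked example: droplet generation sweep

```r
g  <- build_flow_focusing()          # 50 um channels, cross junction
m  <- rasterize_geometry(g, 5)       # 5 um grid
st <- prefill_dispersed(initialize_state(m, fluid_pair_params()),
                        c(0, 200, 175, 250))
run <- run_simulation(st, inflow_spec(u_d = 0.005, ratio = 5), t_end = 0.05)
track_droplets(run$components, m)    # one row per detached droplet

# or the scripted campaign over flow-rate ratios:
sweep_flow_ratio("flow_focusing", ratios = c(2, 5, 8),
                 cell_size = 5, t_end = 0.1)
```

The sweep table reports, per ratio, the volume-weighted mean effective
diameter, its CV, the generation frequency and the mean two-phase pressure
difference P_c − P_d; droplet diameter falls and generation frequency
rises with the flow-rate ratio.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/droplamp` (`simulate`,
`experiment ratio-sweep|junctions|step-sweep|buffer|collection`,
`assay calibrate`), configured through YAML files (see `load_config()`).

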