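# dropcenter

Positioning of actomyosin contraction centers in cell-sized droplets:
hydrodynamic centering, stochastic symmetry breaking, and the track
statistics to analyse both.

## The scientific problem

Cell-free extract encapsulated in water-in-oil droplets self-organises into
a persistently contracting actin network that sweeps material into a dense
aggregate around the contraction center. Droplets end up in one of two
configurations: *symmetric* (aggregate at the droplet center) or *polar*
(aggregate at the boundary), and which one wins depends on droplet size —
small droplets polarise, large ones stay centered. Two mechanisms compete:

1. **Hydrodynamic centering.** The network contracts centripetally at a rate
   γ (inward speed grows linearly with distance from the aggregate surface)
   while cytosol seeps through its pores. The relative motion produces Darcy
   friction with density-dependent resistance ζ(ρ) = ζ₀·η·ρ^α. When the
   aggregate sits off-center the network density distribution is skewed (more
   network assembles in the larger far-side volume), the friction no longer
   balances, and the integrated reaction

   F = −∫ ζ(ρ) (V − U) dΩ

   points back toward the center. Solving the coupled steady state
   (∂ρ/∂t + ∇·(ρV) = k_a − k_d ρ for the network; ζ(ρ)(U − V) = −∇P,
   ∇·U = 0 for the cytosol) shows this force acts like a Hookean spring,
   F = −k·d, with k ∝ R³ — centering gets *stronger* in bigger droplets —
   and nearly proportional to the contraction rate γ.

2. **Clutch-mediated decentering.** The network can transiently anchor to
   the droplet boundary ("clutch"): engagement rate k_on = kon0/b,
   release rate k_off = koff0·b, where b is the aggregate-boundary
   clearance. While engaged the aggregate moves at constant speed v toward
   the nearest boundary; disengaged, it relaxes back at rate λ = k/Γ with
   positional noise D_eff. Small droplets engage often and get captured
   (polar, absorbing); large droplets stay centered for long times but the
   centered state is only metastable.

The package implements both models plus the downstream analysis used on
aggregate trajectories: mean-squared displacement (MSD = 6·D·t^α) and
velocity-autocorrelation fits, A/B/C symmetry-breaking event detection,
recentering-curve alignment, and population symmetry classification with
Gaussian-smoothed size-range borders (threshold u = d/R > 0.4). Synthetic
generators (exact-discretisation Ornstein–Uhlenbeck confined walks, directed
breaking runs, step/logistic populations) provide ground-truthed data for
every stage.

Units throughout: µm, min, pN.

## Worked example

```r
library(dropcenter)

p    <- hydro_params()              # calibrated defaults (see vignette)
geom <- droplet_geometry(R = 50, a = 10)

# 1. Hydrodynamic spring: hold the aggregate at d and integrate the
#    Darcy friction at steady state
curve <- force_displacement_curve(p, geom, c(5, 10, 15, 20))
curve
#>   R_um d_um       F_pN
#> 1   50    5  -460.2918
#> 2   50   10  -921.9098
#> 3   50   15 -1385.9962
#> 4   50   20 -1854.1188
fit_spring_constant(curve)
#> <spring_fit> k = 92.52 pN/um (r2 = 1.0000, 4 points)
```

The force is restoring (negative for a +z displacement) and strikingly
linear — an effective spring of ~93 pN/µm for a 50 µm droplet.

```r
# 2. Release a displaced aggregate (magnetic-perturbation twin)
trj <- simulate_recentering(p, geom, d0 = 20, T = 12)
c(peak = -min(trj$v), t_half = recentering_half_time(trj))
#>    peak  t_half
#>    7.27    1.64
```

Peak recentering speed 7.3 µm/min (within the observed 5–10 µm/min band,
which is what calibrated ζ₀) after a brief reorganisation phase, then a
concave-down slowdown into the center.

```r
# 3. Size-dependent symmetry breaking (stochastic clutch population)
pop <- simulate_population(clutch_params(), seq(15, 60, length.out = 90),
                           T = 40, seed = 1)
polar_fraction_by_size(pop, c(15, 30, 45, 60))
#>       bin  n polar_fraction
#> 1 (15,30] 29      0.8275862
#> 2 (30,45] 30      0.2666667
#> 3 (45,60] 30      0.0000000
```

Small droplets polarise, large ones stay centered, with a bimodal
intermediate zone — the experimental localisation pattern.

```r
# 4. Track statistics on synthetic centered-state data
trks <- lapply(1:12, function(i)
  gen_confined_track(D = 0.32, Rc = 3.4, seed = i, droplet_id = i))
compute_msd(trks, fit_window = 5)
#> <msd_result> 12 tracks, alpha = 0.907, D = 0.302 um^2/min (lags <= 5 min), Rc = 3.47 um
```

The fitted anomalous exponent α ≈ 0.91 and Rc ≈ 3.5 µm recover the
construction truth (α just under 1: confinement bends the MSD down within
the 5 min fit window).

## Command line

```sh
dropcenter hydro    --config cfg.json --out out/            # Fig-4-style force/spring tables
dropcenter recenter --config cfg.json --out out/
dropcenter clutch   --config cfg.json --out out/ --seed 7   # population + size borders
dropcenter synth    --config cfg.json --out out/ --seed 7
dropcenter analyze  --config cfg.json --out out/            # MSD / VACF / break events
```

Each command reads one JSON config, writes CSV tables plus a `*_meta.json`
(parameters, seed, summary statistics) and is byte-reproducible for a fixed
config and seed.

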