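# raftreg

Nanoscale ordered lipid domains ("rafts") sit below the diffraction limit,
so their true size cannot be read off a confocal image: the apparent
diameter `d_a` of a tracked domain overestimates the actual diameter `d` by
a constant offset `δ` (scan-time motion blur plus diffraction). Their
mobility, however, still encodes their size. **raftreg** implements the
size-from-mobility analysis for liquid-ordered (LOD) and liquid-disordered
(LDD) domains diffusing in freestanding planar bilayers, along with the
energetic model that explains why 40–120 nm domains in the two membrane
leaflets sit exactly on top of each other (registration).

The package is aimed at membrane biophysicists working with single-particle
tracking of phase-separated model membranes, and at anyone who wants a
tested, reproducible implementation of the generalized Saffman–Delbrück
size analysis.

## The model

A disk of diameter `d` in a thin membrane sheet of surface viscosity `η`
bathed in water (`η_3D`) diffuses with

```
D(d) = A · [ln(2/ε) − γ_e + 4ε/π − (ε²/2)·ln(2/ε)] /
           [1 − (ε³/π)·ln(2/ε) + v·ε^p / (1 + w·ε^q)]
```

where `ε = β·d/u` is the reduced radius, `A = k_BT/(4πhη)`,
`β = η_3D·u/(hη)`, `γ_e = 0.5772`, `p = 2.74819`, `q = 0.61465`,
`v = 0.73761`, `w = 0.52119`, `h` the bilayer thickness and `u = 1 µm` a
reference length. This interpolation is valid for `10⁻³ < ε < 10³`, i.e.
from single lipids up to 20 µm domains. Observed sizes are modelled as
`d_a = d + δ`, and `(A, β, δ)` are fitted jointly to per-domain `(d_a, D)`
pairs obtained from mean-squared-displacement (MSD) analysis of
trajectories. From the fit follow the membrane viscosities
(`η = k_BT/(4πhA)` and `η = η_3D·u/(hβ)`), the true size of the smallest
tracked domain, and the single-lipid extrapolation `D(0.9 nm)` that is
cross-checked against fluorescence correlation spectroscopy (FCS).

Registration energetics compare the rim (line-tension) energy
`w_rim = π·d·Δγ` against the undulation-mediated area coupling
`W_area = w_area·π·d²/4`; the two cross at the critical diameter
`d* = 4Δγ/w_area`.

## Worked example

Simulate the study conditions (29 tracked LODs, 31 tracked LDDs, diameters
log-uniform over 0.04–20 µm, 500 frames at 0.1 s), estimate per-domain
diffusion coefficients, and fit the offset diffusion law per phase:

```r
library(raftreg)

cfg <- sim_config(seed = 42)
sim <- simulate_tracks(cfg)
obs <- estimate_observations(sim$tracks, n_boot = 0)
an  <- run_domain_analysis(obs, loss = "log", n_starts = 3)
an$summary[, c("phase", "A", "beta", "delta", "eta_from_A", "D_single_lipid", "d_min")]
#> # A tibble: 2 × 7
#>   phase     A  beta delta eta_from_A D_single_lipid  d_min
#>   <chr> <dbl> <dbl> <dbl>      <dbl>          <dbl>  <dbl>
#> 1 LOD   0.752 0.329 0.601     0.0862           6.20 0.0358
#> 2 LDD   0.189 0.221 0.423     0.343            1.63 0.0783
```

The generator truths (LOD row: `A = 0.76 µm²/s`, `β = 0.33`,
`δ = 0.57 µm`; LDD row: `A = 0.18`, `β = 0.20`, `δ = 0.46`) are recovered
within the profile confidence intervals:

```r
profile_ci(an$fits$LOD)
#> # A tibble: 3 × 4
#>   term  estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 A        0.752    0.595     1.06
#> 2 beta     0.329    0.228     0.521
#> 3 delta    0.601    0.502     0.631
```

`eta_from_A` is the viscosity of the phase the tracked domains move
through (≈0.086 Pa·s for the disordered phase around LODs, ≈0.34 Pa·s for
the ordered phase around LDDs), `D_single_lipid` the extrapolation to a
0.9 nm tracer (6.2 and 1.6 µm²/s), and `d_min` the true size of the
smallest tracked domain in µm — tens of nanometres, far below the optical
resolution.

Registration energetics with the default elastic parameters:

```r
energy_report(c(40, 120), "cis")
#> # A tibble: 2 × 9
#>       d state dgamma w_area w_area_source w_rim w_area_total d_star dominant
#>   <dbl> <chr>  <dbl>  <dbl> <chr>         <dbl>        <dbl>  <dbl> <chr>
#> 1    40 cis      0.2  0.013 supplied       25.1         16.3   61.5 rim
#> 2   120 cis      0.2  0.013 supplied       75.4        147.    61.5 undulation
```

A 40 nm domain is registered mainly by its rim line tension
(`d < d* ≈ 60 nm`), a 120 nm domain by undulation coupling. In the trans
photoswitch state (`Δγ = 0.07 k_BT/nm`) the crossover drops to
`d* ≈ 20 nm`.

Other entry points: `fit_fcs()` fits the 2D autocorrelation model
`G(τ) = G0/(1 + τ/τ_D)` and converts `τ_D` to `D = r0²/(4τ_D)`;
`registration_report()` segments ordered-domain pixels in two leaflet
channels (Otsu threshold) and scores their overlap as a Jaccard index;
`simulate_images()` and `simulate_fcs()` generate matching synthetic
inputs. Fitted objects support `tidy()`, `glance()`, `predict()` and
`autoplot()`.

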