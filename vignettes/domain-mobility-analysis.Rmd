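---
title: "Sizing nanoscale lipid domains from their mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing nanoscale lipid domains from their mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftreg)
```

## The problem

Liquid-ordered domains (LODs) in phase-separated bilayers are the model
system for membrane rafts, and the question of whether a domain in one
leaflet is matched by a domain in the other (registration) decides which
physical couplings can organize them. Optically, a tracked domain's
apparent diameter $d_a$ exceeds its true diameter $d$ by an offset
$\delta$ contributed by motion during the confocal scan and by
diffraction; for sub-micron domains $\delta$ dominates $d_a$ entirely.
The way out is hydrodynamics: lateral mobility depends on true size, so a
calibrated diffusion law turns measured diffusion coefficients into true
diameters, pushing the effective size resolution to tens of nanometres.

`raftreg` implements that analysis end to end: per-domain diffusion
estimation from trajectories, the generalized Saffman–Delbrück (GSD) fit
with offset, viscosity back-calculation, an FCS cross-check, a
registration index for two-channel images, and the rim-vs-undulation
energetics of registration. A synthetic-data module generates all inputs
with the statistical structure the analysis assumes.

## The diffusion model

For a cylindrical inclusion of diameter $d$ in a membrane of thickness
$h$ and viscosity $\eta$, surrounded by water of viscosity
$\eta_{3D}$, the GSD interpolation reads

$$D(\varepsilon) = A\,
\frac{\ln(2/\varepsilon) - \gamma_e + 4\varepsilon/\pi -
      (\varepsilon^2/2)\ln(2/\varepsilon)}
     {1 - (\varepsilon^3/\pi)\ln(2/\varepsilon) +
      v\,\varepsilon^p/(1 + w\,\varepsilon^q)},
\qquad \varepsilon = \beta\,d/u,$$

with $A = k_BT/(4\pi h\eta)$, $\beta = \eta_{3D}u/(h\eta)$, $u = 1\,\mu m$,
and fixed constants $\gamma_e = 0.5772$, $p = 2.74819$, $q = 0.61465$,
$v = 0.73761$, $w = 0.52119$ (`gsd_constants()`; overriding them requires
an explicit flag). For $\varepsilon \to 0$ the expression reduces to the
classical Saffman–Delbrück logarithm $A(\ln(2/\varepsilon) - \gamma_e)$;
the quoted validity window is $10^{-3} < \varepsilon < 10^3$ and
`reduced_radius()` warns outside it rather than failing, because the
single-lipid extrapolation at $d = 0.9$ nm deliberately sits below the
window ($\varepsilon \approx 3\times10^{-4}$) and the formula remains
smooth there.

The law is strictly decreasing in $d$ over $[10^{-4}, 10^{3}]\ \mu m$,
which makes the inverse well defined; `invert_diameter()` bisects in
log-diameter to a $10^{-9}$ relative residual.

Units are fixed throughout: lengths in µm except $h$ (nm) and energetics
diameters (nm), $D$ in µm²/s, viscosities in Pa·s, energies in $k_BT$.
$k_B = 1.380649\times 10^{-23}$ J/K and $T$ defaults to 295 K (room
temperature); $k_BT$ is always computed from $T$, never cached.

## From trajectories to observations

`compute_msd()` uses the time-averaged, overlapping-pair MSD per track —
the standard single-particle-tracking estimator, chosen over the ensemble
MSD because the analysis needs one $D$ per domain. `fit_diffusion()`
fits $\mathrm{msd} = 4D\tau + b$ by least squares weighted by the pair
counts; the intercept absorbs static localization noise
($b = 4\sigma_{loc}^2$). A negative fitted slope is flagged and excluded
downstream, never clipped to zero, so the estimator stays unbiased in
ensemble averages.

Only tracks compatible with simple diffusion enter the size analysis.
`classify_simple_diffusion()` demands an anomalous exponent (log–log
slope) within $|\alpha - 1| \le 0.2$ *and* a weighted $r^2 \ge 0.9$ of the
linear fit. The thresholds are package choices — the selection criterion
itself is part of the experimental procedure, but no numeric thresholds
come with it — and at these defaults $\ge 95\%$ of genuine Brownian
tracks of $\ge 500$ frames pass while ballistic and confined motion are
rejected. The default fit window is lags 2–10: lag 1 carries the largest
relative localization-noise contribution and is left out, but both window
and thresholds are arguments.

Per-track uncertainties $\sigma_D$ come from a seeded block bootstrap
(blocks of 10 displacement vectors, 200 resamples). One caveat
discovered while validating the pipeline: these $\hat\sigma_D$ are
proportional to each track's *realized* scatter, so weighting the GSD fit
by $1/\hat\sigma_D^2$ systematically favours tracks that happened to
fluctuate low and biases $A$ downward. `run_domain_analysis()` therefore
ignores tracking-derived sigmas by default (`weighting = "none"`);
externally supplied, error-independent uncertainties can be opted in with
`weighting = "sigma"`, and `fit_gsd()` itself always honours a `sigma_D`
column when given one directly.

## Fitting the offset law

`fit_gsd()` estimates $(A, \beta, \delta)$ by bounded nonlinear least
squares of $D_i$ against the model at $d_{a,i} - \delta$, treating $A$
and $\beta$ as independent (their theoretical link through
$\beta k_BT/(4\pi u A) = \eta_{3D}$ is exposed separately as
`eta3d_consistency()`, as a check rather than a constraint). Choices that
matter:

* **Bounds.** $A, \beta > 0$ and $0 \le \delta < \min d_a$, so every
  corrected diameter stays positive. A fit that pushes $\delta$ onto its
  upper bound is flagged `degenerate_delta`.
* **Multi-start.** The three parameters share a curved valley
  (raising $\delta$ can be traded against $A$ and $\beta$), so the
  optimizer restarts from 5 seeded starts jittered ±50% around the
  default initials $A = \mathrm{median}(D)/5$, $\beta = 0.3$,
  $\delta = 0.8\min d_a$; the best objective wins, ties go to the
  smaller $\delta$.
* **Loss.** The default objective is on $D$ directly; `loss = "log"`
  switches to log-space residuals. For data whose noise is multiplicative
  (a fixed *relative* error on $D$, which is what per-track MSD
  estimation produces), the log loss is the correct homoscedastic
  likelihood and in our simulations removes most of the estimator bias —
  it is what the calibration study below uses.
* **Intervals.** The `ci95` field holds Wald intervals from the local
  curvature. On noisy data these undercover badly (the valley again), so
  `profile_ci()` computes profile-likelihood intervals: each parameter is
  profiled with the other two re-optimized, and the interval is where the
  profiled SSE stays below $SSE_{min}(1 + F_{0.95;1,n-3}/(n-3))$, with
  endpoints clamped to the bounds. `bootstrap_fit()` offers
  case-resampling percentile intervals as a third route. In a 200-replicate
  calibration per phase (29 or 31 domains, true diameters log-uniform over
  0.04–20 µm, 10% multiplicative noise on $D$ — the acceptance suite runs
  exactly this), profile intervals cover the generating $(A,\beta,\delta)$
  in well over 90% of replicates, while Wald intervals do not; this is an
  intrinsic property of the curved objective, not a defect of the
  optimizer.

Identifiability deserves one more note: $\delta$ is constrained almost
entirely by the smallest domains. A design with all $d_a \gg \delta$
leaves $\delta$ nearly free (the profile interval widens accordingly —
this is tested), which is why the experimental strategy of photoswitching
domains down to the resolution limit matters for the fit, not just for
the biology.

## Derived quantities

From a fitted phase the package reports both single-parameter viscosity
conversions, $\eta = k_BT/(4\pi h A)$ and $\eta = \eta_{3D}u/(h\beta)$.
The two agree only if the fit satisfies the $\eta_{3D}$ identity exactly;
on real (and realistic synthetic) data they differ, and both are reported
rather than averaged. Tracked domains of one phase move *through* the
other phase, so the LOD-tracking fit characterizes the disordered-phase
viscosity and vice versa. With the reference parameter set
($A = 0.76$, LOD tracking) the $A$-route gives
$\eta \approx 0.085$ Pa·s and with $A = 0.18$ (LDD tracking)
$\eta \approx 0.36$ Pa·s. Published values for this system
(0.108 ± 0.036 and 0.458 ± 0.092 Pa·s) are 20–30% higher than the pure
$A$-route numbers; the derivation behind them is not fully specified
(plausibly a joint use of $A$ and $\beta$), so the package documents the
discrepancy and exposes both conversions instead of tuning either.

`smallest_domain()` propagates the offset uncertainty into
$\min(d_a) - \delta$ in quadrature, flagging non-physical results, and
`corrected_curve()` re-expresses the data and model over true diameters,
including the single-lipid extrapolation ($D(0.9\,\mathrm{nm}) \approx
6.26$ and $1.57$ µm²/s for the two reference parameter sets).

## FCS cross-check

`fit_fcs()` fits the single-component 2D model
$G(\tau) = G_0/(1+\tau/\tau_D)$ and converts
$D = r_0^2/(4\tau_D)$. The beam waist $r_0$ is **not** identifiable from
the curve; it is a required calibration input (default 0.2 µm, a typical
confocal value), and $D$ from real curves is only as good as the supplied
$r_0$. Triplet and anomalous-diffusion terms are out of scope. The
consistency argument the package reproduces: lipid-tracer mobilities
measured by FCS in the two phases (reference values 7.8 and 0.9 µm²/s)
bracket the GSD extrapolations from domain tracking (6.26 and 1.57
µm²/s) on the correct sides.

## Registration index

`segment_domains()` thresholds each channel globally (Otsu) after
optional Gaussian smoothing; ordered domains are the *dim* pixels because
the tracer dyes partition into the disordered phase (`polarity`
configurable). `registration_index()` is the Jaccard overlap of the two
masks — chosen over intensity correlation because the claim being
quantified is coincidence of domain *areas* across leaflets; Manders
coefficients are provided as secondary outputs. No image alignment is
performed: the channels are assumed pixel-registered, as they are when
acquired simultaneously. For independent random masks with area fractions
$f_1, f_2$ the index has expectation $f_1f_2/(f_1+f_2-f_1f_2)$, which the
tests verify; fully registered synthetic pairs score $\ge 0.9$ through
PSF blur and Poisson noise, antiregistered pairs $\le 0.1$.

## Registration energetics

Two couplings can hold a domain in register across the leaflets. The rim
term scales with the perimeter, $w_{rim} = \pi d\,\Delta\gamma$; the
undulation term with the area, $W_{area} = w_{area}\,\pi d^2/4$, with
density

$$w_{area} = \frac{1}{4a^2}\ln\!\left[\frac{(B_S+B_R)^2}{4B_SB_R}\right]
\quad [k_BT/\mathrm{nm}^2],$$

where $B_R, B_S$ are the monolayer splay moduli and $a$ the ultraviolet
cutoff of the undulation spectrum. Both cross at
$d^\* = 4\Delta\gamma/w_{area}$ — an exact algebraic identity that the
tests verify over randomized parameters. Domains are treated as disks
(line tension keeps them circular).

Defaults follow the reference system: $B_R = 20$, $B_S = 10\ k_BT$,
$\Delta\gamma_{cis} = 0.2$ and $\Delta\gamma_{trans} = 0.07\ k_BT$/nm for
the two photoswitch states of the diacylglycerol, and
$w_{area} = 0.013\ k_BT/\mathrm{nm}^2$. Two documented inconsistencies in
the reference values are left unresolved rather than papered over:

* with $a = 1$ nm the formula gives $w_{area} = \ln(9/8)/4 \approx
  0.0295$, not 0.013; the published density back-solves to
  $a \approx 1.5$ nm, consistent only with the statement that $a$ is "of
  order 1 nm". `elastic_params()` therefore carries `w_area` as an
  explicit default (0.013) and computes from the moduli only when
  `w_area = NULL`; every report records which route produced it.
* the published rim/area energies (24.33, 8.33, 73.2, 25.2, 15.56, 144
  $k_BT$ at $d = 40$ and 120 nm) imply unrounded inputs
  ($\Delta\gamma_{cis} \approx 0.194$, $w_{area} \approx 0.0124$); the
  package keeps the rounded published values as defaults and the tests
  compare at 5% to absorb the rounding.

With the defaults, a 40 nm cis-state domain is rim-dominated
($d^\*_{cis} \approx 61.5 \to 60$ nm) and a 120 nm trans-state domain is
undulation-dominated ($d^\*_{trans} \approx 21.5 \to 20$ nm).
$h_R$, $h_S$, $K_A$ and the spontaneous curvatures are stored as
provenance metadata only — they belong to the upstream elastic theory
that produced the $\Delta\gamma$ values, which this package takes as
given inputs.

## The synthetic-data generator

`sim_config()` fixes the study conditions: 29 LODs and 31 LDDs, true
diameters log-uniform over 0.04–20 µm, per-phase generator truths
$A = 0.76/\beta = 0.33/\delta = 0.57$ (LOD tracking) and
$0.18/0.20/0.46$ (LDD tracking). Where the conditions are not dictated by
the reference analysis the defaults are one-time realism choices: 0.1 s
frame interval with 500 frames per track (a ~50 s observation, consistent
with minutes-scale confocal tracking), 0.02 µm localization noise, a
192 px field at 0.1 µm/px with a 0.15 µm PSF and ~200 detected photons
per bright pixel, FCS curves with 64 log-spaced lags and 2%
multiplicative noise.

What the generator emulates: GSD-law-consistent Brownian motion per
domain (`simulate_tracks()`), the constant-offset observation model
$d_a = d + \delta$ exactly, registered or antiregistered dark disks with
PSF blur and Poisson noise (`simulate_images()`, non-overlapping
placement by rejection sampling with an error above a 50% area fill or
$10^4$ failed attempts), and noisy autocorrelation curves with a known
embedded $\tau_D$ (`simulate_fcs()`). Identical seeds give bit-identical
output.

What it does **not** emulate — and therefore what passing tests cannot
certify about real data: the physical origin of $\delta$ (the generator
injects a constant per phase instead of simulating scan-speed smear and
diffraction, so the analysis assumption and the generator assumption are
the same by construction), domain growth, merger and dissolution during
observation, photoswitching kinetics, anomalous or heterogeneous
diffusion within a track, membrane drift, and detector artefacts beyond
Poisson noise. The tracking filter is exercised against ballistic and
confined contaminants, but real rejected-track populations are richer.

## Numerical choices and degenerate inputs

* Diameter inversion: bisection on $\log_{10} d \in [-4, 3]$,
  tolerance $10^{-13}$, residual check at $10^{-9}$ relative; values of
  $D$ outside the attainable range raise an error naming the range.
* `fit_gsd()` ties between equal-objective restarts break toward smaller
  $\delta$; the model floor `pmax(d_a - delta, 1e-12)` only matters for
  trial points during optimization since the bound keeps the optimum
  interior.
* Profile and inner optimizations cap non-finite objectives at a finite
  sentinel so the root-finding never sees `Inf`.
* Degenerate designs are first-class: a single-diameter design leaves
  $\delta$ unidentified (wide profile interval, tested), apparent
  diameters at or below $\delta$ yield flagged non-physical sizes, a
  constant image refuses to segment, two empty masks give an undefined
  (NA) index with a warning.
* Tests run the calibration at 200 replicates per phase and the
  registration/FCS properties at 40–100 seeded replicates; these sizes
  were chosen to keep Monte-Carlo error on the checked proportions a few
  percent.

## Limitations

The diffusion model ignores the height difference between a
leaflet-spanning and a bilayer-spanning inclusion (a ~30% effect on $D$
at single-lipid size, per the literature the reference analysis cites)
and any leaflet-resolved hydrodynamics. $\Delta\gamma$ is an input, not
computed from spontaneous curvatures and elastic moduli. The FCS module
is single-component 2D only. The registration index assumes
pixel-registered channels and two-phase images; it is a readout for the
synthetic and reference imaging geometry, not a general colocalization
framework.
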