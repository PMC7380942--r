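---
title: "Modelling RhoA-Rac1 GTPase dynamics in migrating cells"
author: "RhoRacWaves authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RhoA-Rac1 GTPase dynamics in migrating cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RhoRacWaves)
```

## The model

Mesenchymal cell migration is coordinated by the small GTPases RhoA and
Rac1, which cycle between active GTP-bound and inactive GDP-bound forms
under the control of GEFs and GAPs.  Their crosstalk runs through three
effectors: the formin DIA relays RhoA activation to Rac1 (and feeds back
positively on RhoA), the kinase ROCK relays RhoA to Rac1-inhibiting GAPs,
and the Rac1 effector PAK inhibits RhoA GEFs while feeding back
positively on Rac1.  The package implements this network as a
five-variable dimensionless ODE system for the active fractions
(`rho`, `dia`, `rock`, `rac`, `pak`), with conservation supplying the
inactive fractions.  Every activation and deactivation flux has
Michaelis-Menten form, and every regulatory interaction enters as a
hyperbolic multiplier

$$\alpha_{YX}(a) = \frac{1 + \gamma_{YX}\, a/K_{YX}}{1 + a/K_{YX}},$$

with $\gamma > 1$ for activation, $\gamma < 1$ for inhibition and
$\gamma = 1$ for no interaction.  ROCK's effect on Rac1 sits on the Rac1
*GAP* flux (ROCK activates Rac-GAPs), so net inhibition of Rac1
corresponds to $\gamma_{ROCKRac} > 1$ on that term; this is also what
makes the ATP-competitive ROCK inhibitor Y-27632, which scales active
ROCK by the competitive-binding factor $\beta \le 1$ *inside* that
multiplier, de-repress Rac1.  The allosteric PAK inhibitor IPA-3 binds
the inactive PAK conformation and enters solely as a scaling of the PAK
activation constant, `kaPAK * (1 + dose/K_I)`.

Spatially, the model becomes a reaction-diffusion system: active
(membrane-bound) and inactive (cytosolic) GTPase forms diffuse with
different coefficients, effectors do not diffuse, and the DIA and ROCK
totals vary along the cell's long axis.  With the cell oriented rear
(x = 0) to front (x = L), the DIA total ramps linearly up toward the
leading edge and the ROCK total is high on the rear/body segment and low
on the front segment; this orientation convention (DIA front-high, ROCK
rear-high) is fixed throughout the package, matching the polarized
localization of the two effectors that motivates the profiles.

## The calibrated parameter set

No published numeric parameter table pins down every rate constant of
this effector-mediated RhoA-Rac1 network, so the package ships its own
calibrated set (`defaultKineticParams()`), constructed to satisfy the
qualitative constraints that define the biology and then frozen:

* the unperturbed point (DIA, ROCK) = (1, 1) is a single unstable focus
  surrounded by a stable limit cycle with a period near one minute
  (regime 1, the leading-edge oscillator);
* increasing ROCK at fixed DIA enters the BiDR regime (stable cycle
  coexisting with a high-RhoA/low-Rac1 node behind a saddle), and a
  further band with the same census but no cycle (excitable);
* the low-DIA/high-ROCK corner used for the cell rear holds a stable
  high-RhoA/low-Rac1 state and no limit cycle;
* reducing total PAK quenches the oscillation and leaves a single
  high-RhoA steady state (the amoeboid end point of PAK inhibition);
* RhoA and Rac1 abundances exceed the effector abundances more than
  tenfold, which justifies both the effector-complex linearization and
  the quasi-steady-state reduction.

Mechanistically, the calibration makes DIA and ROCK fast, nearly
zero-order activation switches (small Michaelis constants), while PAK is
the slow variable that paces the relaxation oscillation.  Two choices
deserve comment.  First, the PAK activation constant `kaPAK` is large
(0.6 on the fraction scale), so the rate of PAK activation genuinely
depends on how much inactive PAK is available; lowering the PAK total
therefore *raises* the Rac1 level needed to ignite PAK.  This single
mechanism lets IPA-3 (which scales `kaPAK`) act exactly like PAK
depletion, and it separates the oscillatory regime at full PAK from the
monostable high-RhoA regime at low PAK.  Second, the ROCK-to-Rac
modifier operates in its near-linear range (`kROCKRac = 6`), so the
ROCK *abundance* axis retains leverage instead of saturating.

Rates are in 1/s and all concentrations are fractions of the respective
totals; the abundances (`Rhotot` etc.) matter only for
nondimensionalization and the effector-complex module.  The set is
stored as a flat YAML file in `inst/extdata/params_default.yaml` and can
be loaded or replaced with `readKineticParams()`.

## Numerical choices

* **Well-mixed integration** uses the embedded fifth-order Cash-Karp
  Runge-Kutta scheme (via \pkg{deSolve}) with `rtol = 1e-7`,
  `atol = 1e-9`.
* **Steady states** come from damped Newton iterations started on a
  deterministic 3-level lattice (0.05/0.5/0.95 of each species total,
  243 starts) plus the endpoints of four corner integrations; roots are
  deduplicated at `1e-6` and accepted below a residual of `1e-9`.
  Stability is read off central-difference Jacobian eigenvalues with a
  `1e-8` zero threshold; borderline points are reported as unclassified
  rather than guessed.
* **Limit cycles** are detected by long integration with the first half
  discarded, requiring at least five successive activity peaks with
  amplitude above 1% of the total and an inter-peak coefficient of
  variation below 5%.  This matches a phase-portrait approach in which
  non-local bifurcation borders (e.g. the homoclinic loss of the cycle)
  emerge from simulation rather than from numerical continuation.
* **The spatial solver** uses a structured regular grid with a
  mask-aware 5-point stencil and zero-flux boundaries in place of
  unstructured finite volumes; behaviour is governed by reaction
  kinetics and isotropic diffusion, and grid convergence is tested.
  Time stepping is Strang splitting: half-step implicit diffusion
  (sparse Cholesky, unconditionally stable), a full reaction step
  advanced pixel-wise by an adaptive Cash-Karp integrator in compiled
  code, then another diffusion half-step.  Because the reaction step
  conserves each pixel's GTPase totals exactly and the zero-flux
  Laplacian has zero column sums, global GTPase mass is conserved to
  round-off.
* **Default problem sizes** are 200 nodes for 1-D runs, masks
  downsampled to at most 60 x 120 pixels for 2-D runs, and a 1-s
  splitting step; these resolve the wave structure while keeping a full
  movement-cycle simulation in the seconds-to-minutes range.

## What the default simulation shows

With the default profiles the leading edge oscillates with a period
near one minute while the rear holds high RhoA; the oscillatory zone
spreads slowly rearward and leaves a low-RhoA "dark zone" between the
wave train and the high-RhoA rear, before the pattern settles into a
pinned front oscillator.  The protocol window for region-resolved burst
counting (`movementCycleWindow()`) is therefore centred on the phase in
which the RhoA activity wave arrives at the rear segment: there the rear
experiences its one or two RhoA excursions per ten minutes, while the
front bursts about once a minute.  Because the cell lacks retraction
mechanics, the model does not reset into a new movement cycle on its
own; the cycle's wave-arrival phase is the part of the experimentally
observed cycle that the chemistry alone reproduces, and later windows
show a stationary division of labour (front bursts, quiet rear) instead.

```{r, eval = FALSE}
sol <- simulate1d(nNodes = 200, tMax = 1200, outputDt = 5)
countBurstsByRegion(sol, window = movementCycleWindow(sol))
plotKymograph(buildKymograph(sol))
```

## Analysis conventions

* **Bursts.**  Burst counts from biosensor imaging are usually reported
  without an operational definition, so the package declares one: an upward
  crossing of `baseline + 0.5 * (max - baseline)` (baseline = 10th
  percentile) with a 20-s refractory time.  A series whose total range
  is below `minRange = 0.1` (the typical ratiometric-biosensor noise
  floor, also the default noise of the synthetic movie generator) is
  treated as quiescent.  All thresholds are arguments.
* **Regions** reuse the 10/70/20 front/middle/rear segmentation of the
  PLA quantification throughout, so imaging-derived and model-derived
  numbers refer to the same compartments.
* **Oscillatory centers.**  A center is a domain oscillating with one
  rhythm.  Candidate pixels (peak-to-peak Rac1 amplitude at least half
  the global maximum) are clustered by dominant period: a single
  pacemaker entrains its whole wave train to one frequency, so a
  connected wave field counts once, whereas ROCK inhibition leaves the
  front and the rear/body running at incommensurate periods, which
  appear as separate frequency plateaus.  Amplitude-maximum clustering
  alone cannot make this distinction (every antinode of one wave train
  is a local maximum), which is why the frequency criterion is primary
  and `minSeparation` only merges near-coincident centers.
* **Hysteresis** ramps PAK (or IPA-3 dose) down and back up, chaining
  each level's final state into the next and averaging activities over
  space and the second half of each fixed-horizon level.  Levels of
  1000-1500 s with a 50% transient cut are enough for the branch means
  to stabilize; branches over monostable ladders coincide to numerical
  precision, which is the built-in control for the horizon choice.

## The synthetic data generators

`generateCellMask()` draws ellipse or teardrop (wide end = front) masks
with a seeded low-frequency boundary perturbation;
`renderFretMovie()` emulates ratiometric biosensor imaging of a
simulation (resampling to the 5-s imaging cadence, exponential
photobleaching, multiplicative Gaussian noise) and carries the noiseless
burst times as ground truth; `generatePlaPattern()` draws
proximity-ligation-like point patterns as homogeneous Poisson processes
per 10/70/20 segment, with front-biased RhoA-DIA and rear-biased
RhoA-ROCK presets.  These emulate the *statistics* the imaging assays
report (per-segment densities, burst counts), not the physics of FRET
or the PLA chemistry: passing round-trip tests shows the analysis code
is unbiased under the stated noise model, not that it is robust to
channel misregistration, photobleaching nonlinearity, or segmentation
error in real movies.

## Design decisions and limitations

* The canonical variables are the dimensionless fractions; dimensional
  concentrations are recovered by multiplying with the stored totals.
* The regime taxonomy 0-8 is assigned from the steady-state census and
  the limit-cycle flag; a census matching no pattern is returned as
  unclassified with diagnostics.  Under the calibrated defaults the
  bistable atlas points pair a stable *focus* with the high-RhoA node
  (regime 4); censuses with two stable nodes (regimes 7/8) do not occur
  on the scanned planes, so bistability anchors use the regime-4
  points.
* The PAK ramp at unperturbed abundances passes directly from the
  oscillatory regime to the monostable high-RhoA regime; the open
  hysteresis loop lives on ladders anchored in the BiDR band (elevated
  ROCK), where the cycle and the high-RhoA node genuinely coexist.
* Deterministic, y-symmetric 2-D simulations entrain to a single wave
  system; multi-polar shapes driven by stochastic lamellipodium
  nucleation and boundary motion are outside the model, and the
  multi-center analysis therefore runs on the 1-D protocol where the
  frequency splitting under ROCK inhibition is unambiguous.
* No cell mechanics: protrusion, retraction and shape change are not
  fed back into the domain, so a full autonomous movement cycle
  (including the rear reset) is not closed; wave interactions with a
  deforming boundary are explicitly out of scope.
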