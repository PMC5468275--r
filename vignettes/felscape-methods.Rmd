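---
title: "Free-energy landscapes from simulation samples: methods and design"
author: "felscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy landscapes from simulation samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felscape)
```

## The problem

Atomistic simulations of reactive events — here, ATP hydrolysis in the
cohesin ATPase head and the subsequent separation of its Smc1A/Smc3 head
domains — produce two kinds of raw material: large tables of sampled
conformations tagged with a reaction-coordinate value and a potential
energy, and steered-pulling trajectories in which a harmonic restraint
drags a coordinate at constant velocity.  felscape turns the first into
free-energy surfaces, minimum-energy paths and reaction barriers, and the
second into Jarzynski free-energy difference profiles, with bootstrap
errors throughout.  Because no deposited trajectory data exist for such
systems at desk scale, the package carries a first-class synthetic-data
module: analytic model potentials with Langevin, steered-pulling and
Metropolis engines whose exact ground truth every estimator is tested
against.

## Free-energy estimation

Samples are binned on a uniform grid (half-open bins `[lo, hi)`, last bin
closed, edge ties upward).  Each occupied bin's free energy is the
partition-function estimate

$$\Delta G_{\mathrm{bin}} = E_{\min} - k_B T \,\log\!\Big(\tfrac{1}{N}\sum_i
e^{-(E_i - E_{\min})/k_B T}\Big),$$

computed with a log-sum-exp shift so spreads of hundreds of kcal/mol stay
finite.  Dividing by the bin count $N$ makes the estimate insensitive to
how densely a steered protocol happened to sample each region; the
alternative (no normalization) differs by $k_B T \log N_{\mathrm{bin}}$
and would imprint the sampling schedule on the surface, which is why we
chose the normalized form.  The estimate always lies in
$[E_{\min}, E_{\min} + k_B T \log N]$ and tends to the arithmetic mean of
the bin energies at high temperature.

Occupied bins are then smoothed by LOESS (tri-cube weights over the
span-nearest neighbours, local polynomials, via `stats::loess` with the
exact "direct" surface).  Defaults are span 0.25 and degree 2; sources in
this field rarely state their smoothing parameters, so both are explicit,
logged settings.  Unoccupied bins are excluded from the fit and stay
missing — nothing supports an extrapolated free energy there.  The global
minimum of the smoothed occupied surface is subtracted, so surfaces are
reported relative to their deepest basin.  Grid sizes default to 48×48
(2D) and 100 (1D); the reference workflow quotes only a mean group
occupancy (~1.5×10⁴ samples per occupied bin from 7.6×10⁶ samples), which
these defaults reproduce in spirit.

1D profile workflows that relax windows along a steered coordinate keep
only each window's converged tail; `windowTailSelection` keeps the frames
in `(t_end - tail, t_end]`, by duration, with a 10% default (0.5 ps of a
5 ps relaxation).

Errors come from bootstrap resampling of the sample rows (default 100
replicates, the convention in this literature), rerunning the full
binning–estimation–smoothing pipeline per replicate, and reporting the
per-bin SD.  A zero-variance input yields an exactly zero SD map.

## Minimum-energy paths

On a gridded surface the chemically meaningful path between two basins is
the one whose *highest* point is lowest: a minimax criterion, equivalent
for barrier heights to the node-by-node flooding used by grid-based path
tools.  `minimumEnergyPath` solves it with a minimax Dijkstra pass, then
breaks ties among minimax-optimal paths by a second, additive Dijkstra
(smallest summed node free energy) restricted to nodes at or below the
flooding level, with deterministic lexicographic scanning.  Missing bins
are impassable, not "infinitely high but traversable": a route through
never-sampled territory is not evidence.  Connectivity defaults to
8-neighbour (diagonal arcs advance by √2 × bin width).  The barrier is the
path maximum minus the starting-basin value; the main transition state is
the global path maximum, and intermediate transition states are other
local maxima with topographic prominence ≥ 0.5 kcal/mol by default —
about $k_B T$ at 300 K, so wiggles smaller than thermal noise are not
called transition states.

## Jarzynski analysis of steered pulling

For a trace with spring constant $k$, coordinate $x(t)$ and restraint
center $c(t)$, the pulling force is $F = k\,(c - x)$ and the external work
is the line integral of $F$ over the *center* displacement (trapezoidal
over frames).  Holds contribute zero work because the center does not
move.  Work series are interpolated onto a common displacement grid
(0.1 Å spacing) and combined by

$$\Delta G(s) = -k_B T\,\log \tfrac{1}{N} \sum_i e^{-W_i(s)/k_B T},$$

again log-sum-exp stabilized.  $\Delta G(0) = 0$ exactly, a single
trajectory returns its own work profile, and Jensen's inequality
($\Delta G \le \langle W \rangle$) holds for every ensemble.  Percentile
bootstrap over trajectories provides the confidence band.  Two conditions
are compared pointwise, with the scalar readout at the final common
displacement — the head-separation ΔΔG convention; for a force peak at
intermediate separation the full ΔΔG profile is available, so both
readouts can be inspected rather than guessing which one a summary number
refers to.

## Time-series statistics

`occupancyFraction` reports the percentage of frames at or below a
distance cutoff, inclusive at the cutoff.  The default 3.5 Å is the
heavy-atom hydrogen-bond criterion (the same bound used for catalytic
water restraints); because published occupancy percentages rarely state
their cutoff, it is an explicit argument and `occupancySensitivity`
reports a sweep over 3.0–4.0 Å instead of asserting a single number.
`stabilizedValue` averages the final window of a series (default: last
20%).  `superposeRmsd` performs the standard least-squares rigid
superposition (SVD-based, determinant forced to +1 so reflections are
excluded) with correspondence by point order; `rmsdSeries` applies it
frame by frame so rigid tumbling contributes nothing.

## The synthetic-data module

The generators emulate the statistical structure of the real inputs, not
their physics:

* **Potentials** — harmonic (1D/2D), a symmetric quartic double well
  $h((x/a)^2-1)^2$, the standard Müller–Brown four-Gaussian landscape
  (literature coefficients, read in kcal/mol and Å; reference global
  minimum −146.6995 at (−0.558, 1.442), recorded after dense grid search
  with local refinement), and arbitrary 1D polynomials.
* **Dynamics** — overdamped Euler–Maruyama,
  $x \leftarrow x - \nabla U\,dt/\gamma + \sqrt{2 k_B T\,dt/\gamma}\,\xi$:
  the simplest integrator whose stationary law is the Boltzmann
  distribution, which is all the estimators need.  Stability requires
  $dt\,k/\gamma \ll 1$ for the stiffest force constant $k$; the integrator
  aborts with the failing step number if a coordinate diverges past a
  guard.  $k_B$ = 0.0019872041 kcal mol⁻¹ K⁻¹; default temperature 300 K,
  the production temperature of the simulations being emulated.
* **Boltzmann samples** — Metropolis random walk with Gaussian proposals,
  10% burn-in and thinning 10.  The real conformations come from steered
  QM/MM sampling, which we do not imitate beyond the coordinate+energy
  row structure; the normalized bin estimator above is what makes that
  acceptable.
* **Steered pulling** — piecewise-linear center schedule
  (hold / constant velocity / hold), mirroring constant-velocity SMD with
  end-state holds.  The reference separation protocol (2.5 Å/ns over
  13 ns, spring 5 kcal mol⁻¹ Å⁻², 0.1 ns holds, 32.5 Å total) is
  reproduced by the schedule exactly; tests and the acceptance script
  pull smaller model systems (e.g. 1.5 Å over 2 ns on a harmonic well
  with a stiff 200 kcal mol⁻¹ Å⁻² spring, 25 trajectories) so the
  analytic answer is known and runs take seconds.
* **Two-state distances** — Gaussian emission around the active state's
  mean with toggles at given frames, clipped at zero; only trace plots
  exist for the real observable, so Gaussian emission is a modelling
  choice, not a fit.
* **Flat-bottom restraints** — zero inside `[lower, upper]`, half-harmonic
  walls outside (the functional form is unstated in the sources; half
  harmonic is the common convention and is continuous and once
  differentiable at the walls).

Every stochastic generator is driven by R's RNG after `set.seed`, so a
seed fixes the output bit for bit.

What passing tests on this synthetic data does *not* show: convergence on
rugged all-atom landscapes, force-field fidelity, or the adequacy of any
particular reaction-coordinate choice.  The synthetic landscapes are
smooth and low-dimensional by design; they validate the estimators'
arithmetic, conventions and convergence behaviour, not the physics
upstream of them.

## Numerical choices and degenerate inputs

* Log-sum-exp shifts in both exponential averages (bin partition
  functions and Jarzynski).
* Half-open binning with edge ties upward; the single value exactly at
  the grid maximum joins the last bin.
* Out-of-range samples are dropped with a warning and counted, never
  silently clipped.
* Degree-2 LOESS falls back to degree 1 with a warning on rank-deficient
  local fits; too few occupied bins for the requested degree is an error.
* Paths: ties in the minimax level are broken by summed node energy, then
  by deterministic lexicographic scan order; disconnected endpoints give
  an error that names the maximum occupied level.
* Superposition warns on near-collinear point sets (rotation
  ill-determined) and refuses fewer than three points.
* `windowTailSelection` treats each frame as representing one sampling
  period, so a 10 000-frame window of 5 ps keeps exactly 1 000 frames for
  a 0.5 ps tail, and a tail equal to the window duration is the identity.

## Problem sizes used in the checks

The test suite and acceptance script size their simulations to validate
each claim at the smallest scale where the statistics are decisive:
10⁶ Metropolis samples for surface recovery (48×48 grid, errors ≲ 0.1
kcal/mol on bins with ≥ 200 samples), 10⁶ Langevin steps for
equipartition, 25 pulling trajectories for Jarzynski recovery (≈ 1%
error), 1 000 random grids against the exhaustive path-enumeration
oracle, and 100 bootstrap replicates (the field's convention).

## A worked example

```{r example, eval = FALSE}
library(felscape)

## reaction mapping on a known double well
tb <- boltzmannSamples(doubleWellPotential(height = 3), n = 2e5,
                       seed = 2, stepSd = 0.4)
profile <- estimateProfile1d(tb)
profileBarrier(profile)$barrier     # ~3 kcal/mol

## head-separation analysis on a harmonic stand-in
pull <- function(i) accumulateWork(simulateSMD(
  harmonicPotential(k = 2), thermostatParams(friction = 50, timeStep = 0.005,
                                             seed = i, steps = 1L),
  spring = 200, startCenter = 0, velocity = 0.75, duration = 2,
  hold = 0.01, stride = 10))
res <- jarzynskiBootstrap(lapply(1:25, pull), temperature = 300, seed = 1)
res@dg[length(res@dg)]              # ~2.23 vs analytic 2.25 kcal/mol
```

## Known limitations

* The Boltzmann sampler is a single-chain random walk: it will not cross
  barriers many times $k_B T$ high, so multi-basin surfaces are explored
  one basin at a time (as with the Müller–Brown landscape at 300 K).
  This matches the intended use — estimator validation — but not global
  exploration.
* The Jarzynski estimator inherits the usual finite-N bias when
  dissipation is large; the quasi-static diagnostic (`meanWorkProfile`
  gap) is provided, but no bidirectional or cumulant-corrected estimator
  is included by default.
* Path extraction operates on the grid; no continuous-space string or
  nudged-elastic-band refinement is attempted.
* No PDB/DCD parsing: coordinate frames enter as labelled matrices.
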