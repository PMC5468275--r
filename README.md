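# felscape

Free-energy landscape estimation and path analysis for biomolecular
simulation data, in R.

Simulations of reactive events in protein machines — the motivating system
is ATP hydrolysis and head-domain separation in the human cohesin
Smc1A/Smc3/Rad21 ATPase head — produce energy-tagged reaction-coordinate
samples and steered-pulling trajectories. felscape converts these into the
quantitative readouts such studies report:

* **Free-energy surfaces and profiles.** Samples are binned on a uniform
  grid; each bin's free energy is the partition-function estimate
  ΔG = E_min − k_B·T·ln( (1/N) Σᵢ e^−(Eᵢ−E_min)/k_BT ), smoothed by LOESS
  over occupied bins, zero-referenced at the deepest basin, with bootstrap
  SD maps (100 replicates by default).
* **Minimum-energy paths and barriers.** On a gridded surface the
  substrate→product path minimizes its highest point (minimax flooding
  criterion); the barrier is ΔG‡ = max over the path − ΔG(S), with main and
  intermediate transition states located by topographic prominence.
* **Jarzynski free-energy differences.** From constant-velocity pulling
  traces the package reconstructs forces F = k(c − x) and accumulated work
  W(s) = ∫ F dc, and estimates
  ΔG(s) = −k_B·T·ln ⟨e^−W(s)/k_BT⟩ with percentile bootstrap CIs and
  condition comparisons (ΔΔG).
* **Trajectory statistics.** Threshold-occupancy percentages (inclusive
  cutoff), stabilized-distance readouts and optimal-superposition RMSD
  series (Kabsch, reflection-guarded).
* **Synthetic ground truth.** Analytic model potentials (harmonic,
  double-well, Müller–Brown), flat-bottom restraints, overdamped Langevin
  and steered-pulling integrators and a Metropolis Boltzmann sampler —
  seed-deterministic generators against which every estimator is tested.

## A worked example

```r
library(felscape)

## 1. Reaction mapping: recover a known 3 kcal/mol double-well barrier
tb <- boltzmannSamples(doubleWellPotential(height = 3), n = 2e5,
                       seed = 2, stepSd = 0.4)
profile <- estimateProfile1d(tb)           # 100 bins, LOESS span 0.25
profileBarrier(profile)$barrier
#> [1] 2.996181

## 2. Head-separation energetics: stiff-spring pulling on a harmonic well
pull <- function(i) accumulateWork(simulateSMD(
  harmonicPotential(k = 2), thermostatParams(friction = 50, timeStep = 0.005,
                                             seed = i, steps = 1L),
  spring = 200, startCenter = 0, velocity = 0.75, duration = 2,
  hold = 0.01, stride = 10))
res <- jarzynskiEstimate(lapply(1:25, pull), temperature = 300)
res@dg[length(res@dg)]                     # analytic value: 2.25 kcal/mol
#> [1] 2.276384

## 3. Occupancy of an active-site contact
s <- twoStateDistanceSeries(2.5, 7.9, noiseSd = 0.3, switchTimes = 63001,
                            totalFrames = 1e5, seed = 17)
occupancyFraction(s, cutoff = (2.5 + 7.9) / 2)
#> [1] 63
```

The first number is the estimated well-to-well barrier of the synthetic
double well (analytic value 3); the second is the Jarzynski estimate of
the free-energy change for dragging a particle 1.5 Å up a harmonic well
(analytic value 2.25 kcal/mol, so the estimator is within ~1%); the third
recovers the generator's 63% bound-state dwell fraction from the distance
series alone.

Two end-to-end drivers, `runReactionWorkflow()` and
`runSeparationWorkflow()`, chain these stages and write TSV outputs plus a
manifest JSON (tool version, config hash, seed). A thin command-line
front end with the same capabilities ships in `inst/scripts/felscape`.

The methods vignette (`vignettes/felscape-methods.Rmd`) documents the
estimators, their conventions and the design decisions.

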