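# Synthetic-data generators: overdamped Langevin trajectories, steered
# (moving-restraint) pulling runs, Metropolis Boltzmann sampling and
# two-state distance series.  All randomness goes through the R RNG after
# set.seed(), so identical seeds give bit-identical output.

#' Thermostat / integrator parameters
#'
#' @param temperature bath temperature (K); default 300 K.
#' @param friction friction coefficient of the overdamped Euler-Maruyama
#'   update \eqn{x \leftarrow x - \nabla U\, dt/\gamma +
#'   \sqrt{2 k_B T dt/\gamma}\,\xi} (kcal mol-1 ps A-2).
#' @param timeStep integration time step (ps).  For stability keep
#'   \code{timeStep * k / friction} well below 1 for the stiffest harmonic
#'   constant k in the system; the integrator aborts if a coordinate
#'   diverges.
#' @param seed RNG seed.
#' @param steps number of integration steps.
#' @return a \linkS4class{ThermostatParams}.
#' @export
thermostatParams <- function(temperature = 300, friction = 5, timeStep = 0.01,
                             seed = 1L, steps = 10000L) {
  new("ThermostatParams", temperature = as.numeric(temperature),
      friction = as.numeric(friction), timeStep = as.numeric(timeStep),
      seed = as.integer(seed), steps = as.integer(steps))
}

#' Simulate an overdamped Langevin trajectory
#'
#' Integrates overdamped Euler-Maruyama dynamics on an analytic potential,
#' optionally with flat-bottom restraints on the simulated coordinates.  At
#' temperature 0 started at a stationary point the coordinates stay put;
#' the stationary distribution at temperature T is Boltzmann under the
#' combined potential.
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param params a \linkS4class{ThermostatParams}.
#' @param start starting coordinates (length = potential dimensionality).
#' @param restraints list of \linkS4class{FlatBottomRestraint} on "rc1"/"rc2".
#' @param guard divergence guard: the run aborts with an error naming the
#'   step if any |coordinate| exceeds this value.
#' @return a \linkS4class{Trajectory} with \code{steps + 1} frames (the
#'   start at t = 0 plus one per update).
#' @export
simulateLangevin <- function(spec, params, start, restraints = list(), guard = 1e4) {
  stopifnot(is(spec, "PotentialSpec"), is(params, "ThermostatParams"))
  start <- as.numeric(start)
  if (length(start) != spec@dimension)
    stop("start must match the potential dimensionality", call. = FALSE)
  pk <- .cppPack(spec)
  rmat <- .restraintMatrix(restraints, spec@dimension)
  set.seed(params@seed)
  res <- .cppLangevin(pk$fam, pk$par, rmat, kBoltzmann * params@temperature,
                      params@friction, params@timeStep, params@steps, start, guard)
  colnames(res$coords) <- paste0("rc", seq_len(spec@dimension))
  new("Trajectory", times = res$times, coords = res$coords, energies = res$energies)
}

#' Simulate a constant-velocity steered-pulling trajectory
#'
#' A harmonic restraint of stiffness \code{spring} is attached to the (1D)
#' coordinate; its center is held at \code{startCenter} for \code{hold} ns,
#' moved at \code{velocity} for \code{duration} ns, then held again for
#' \code{hold} ns, mirroring the constant-velocity pulling protocol of
#' steered MD.  Per-frame time, coordinate and restraint center are
#' recorded.
#'
#' @inheritParams simulateLangevin
#' @param spring restraint spring constant (kcal mol-1 A-2).
#' @param startCenter initial restraint center (Angstrom).
#' @param velocity pulling velocity (A ns-1); may be 0.
#' @param duration constant-velocity segment duration (ns).
#' @param hold hold duration at start and end (ns).
#' @param start starting coordinate; defaults to \code{startCenter}.
#' @param stride record every \code{stride}-th step (the first and last
#'   steps are always recorded).
#' @return an \linkS4class{SMDTrace}; times are in ns.
#' @export
simulateSMD <- function(spec, params, spring, startCenter, velocity, duration,
                        hold = 0, start = startCenter, stride = 1L, guard = 1e4) {
  stopifnot(is(spec, "PotentialSpec"), is(params, "ThermostatParams"))
  if (spec@dimension != 1L)
    stop("steered pulling is defined for 1D potentials", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (hold < 0) stop("hold must be >= 0", call. = FALSE)
  dt <- params@timeStep                      # ps
  hold_steps <- as.integer(round(hold * 1000 / dt))
  ramp_steps <- as.integer(round(duration * 1000 / dt))
  if (ramp_steps < 1L) stop("duration shorter than one time step", call. = FALSE)
  pk <- .cppPack(spec)
  set.seed(params@seed)
  res <- .cppSmd(pk$fam, pk$par, kBoltzmann * params@temperature, params@friction,
                 dt, spring, startCenter, velocity / 1000, hold_steps, ramp_steps,
                 as.integer(stride), start, guard)
  # actual ramp duration after rounding to whole steps
  ramp_ns <- ramp_steps * dt / 1000
  hold_ns <- hold_steps * dt / 1000
  new("SMDTrace", times = res$times / 1000, coord = res$coord,
      center = res$center, spring = as.numeric(spring),
      velocity = as.numeric(velocity), holdDuration = hold_ns,
      rampDuration = ramp_ns)
}

#' Draw Boltzmann-distributed samples from a model potential
#'
#' Metropolis random walk targeting \eqn{\exp(-U/k_B T)}, with isotropic
#' Gaussian proposals, 10% burn-in and thinning (defaults per the module's
#' design).  Every returned row carries the exact potential energy at its
#' coordinates, mimicking the coordinate+energy structure of
#' reaction-coordinate sampling in QM/MM simulations.
#'
#' @param spec a \linkS4class{PotentialSpec}.
#' @param temperature sampling temperature (K); must be > 0.
#' @param n number of samples to keep.
#' @param seed RNG seed.
#' @param stepSd proposal standard deviation (Angstrom).
#' @param thin keep every \code{thin}-th post-burn-in state.
#' @param burnFraction burn-in length as a fraction of the kept-chain length.
#' @param start starting point; defaults to the origin (harmonic center /
#'   Mueller-Brown global minimum for those families).
#' @return an \linkS4class{EnergySampleTable}.
#' @export
boltzmannSamples <- function(spec, temperature = 300, n, seed = 1L, stepSd = 0.1,
                             thin = 10L, burnFraction = 0.1, start = NULL) {
  stopifnot(is(spec, "PotentialSpec"))
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(start)) {
    start <- switch(spec@family,
      harmonic = spec@params$center,
      double_well = spec@params$halfSeparation,
      mueller_brown = muellerBrownMinimum()$x,
      rep(0, spec@dimension))
  }
  start <- as.numeric(start)
  if (length(start) != spec@dimension)
    stop("start must match the potential dimensionality", call. = FALSE)
  pk <- .cppPack(spec)
  total <- as.numeric(n) * thin
  burn <- as.integer(ceiling(burnFraction * total))
  set.seed(seed)
  res <- .cppMetropolis(pk$fam, pk$par, kBoltzmann * temperature, as.integer(n),
                        as.integer(thin), burn, as.numeric(stepSd), start)
  colnames(res$coords) <- paste0("rc", seq_len(spec@dimension))
  new("EnergySampleTable", rc = res$coords, energy = res$energies)
}

#' Construct an energy-sample table
#'
#' @param rc1 first reaction-coordinate values (Angstrom).
#' @param energy per-sample energies (kcal/mol).
#' @param rc2 optional second reaction coordinate.
#' @return an \linkS4class{EnergySampleTable}.
#' @export
energySampleTable <- function(rc1, energy, rc2 = NULL) {
  rc <- if (is.null(rc2)) cbind(rc1 = as.numeric(rc1))
        else cbind(rc1 = as.numeric(rc1), rc2 = as.numeric(rc2))
  new("EnergySampleTable", rc = rc, energy = as.numeric(energy))
}

#' Two-state distance time series
#'
#' Emulates a distance observable that switches between a bound-like and an
#' unbound-like state: Gaussian noise around the mean of whichever state is
#' active at each frame, clipped at 0.  The series starts in state A and
#' toggles at each switch frame.
#'
#' @param meanA,meanB state means (Angstrom, > 0).
#' @param noiseSd Gaussian emission SD (Angstrom).
#' @param switchTimes frame indices (1-based) at which the active state
#'   toggles; may be empty.
#' @param totalFrames number of frames.
#' @param seed RNG seed.
#' @param dt frame spacing (ns) for the time axis.
#' @param label observable label.
#' @return a \linkS4class{DistanceSeries}.
#' @export
twoStateDistanceSeries <- function(meanA, meanB, noiseSd, switchTimes = integer(),
                                   totalFrames, seed = 1L, dt = 0.001,
                                   label = "two-state distance") {
  stopifnot(meanA > 0, meanB > 0, noiseSd >= 0, totalFrames >= 1)
  switchTimes <- sort(as.integer(switchTimes))
  state <- cumsum(tabulate(switchTimes, nbins = totalFrames)) %% 2L  # 0 = A, 1 = B
  mu <- ifelse(state == 0L, meanA, meanB)
  set.seed(seed)
  d <- pmax(mu + rnorm(totalFrames, sd = noiseSd), 0)
  new("DistanceSeries", times = dt * seq_len(totalFrames), distances = d,
      label = label)
}

#' State assignment of a two-state series
#'
#' Ground-truth helper: the active state (\code{"A"}/\code{"B"}) per frame
#' for the switch schedule used by \code{\link{twoStateDistanceSeries}}.
#'
#' @inheritParams twoStateDistanceSeries
#' @export
twoStateAssignment <- function(switchTimes = integer(), totalFrames) {
  switchTimes <- sort(as.integer(switchTimes))
  state <- cumsum(tabulate(switchTimes, nbins = totalFrames)) %% 2L
  c("A", "B")[state + 1L]
}
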