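# S4 containers for the whole pipeline.  Validity methods enforce the
# structural invariants; accessors (AllGenerics.R / accessors below each
# class) are the supported way to reach slots.

#' @title Analytic model potential
#' @description Specification of an analytic potential-energy function used
#'   as ground truth by the synthetic-data module.  Supported families:
#'   \code{"harmonic"} (1D or 2D), \code{"double_well"} (1D quartic),
#'   \code{"mueller_brown"} (the standard four-Gaussian 2D landscape) and
#'   \code{"polynomial"} (1D, arbitrary coefficients).  Energies are in
#'   kcal/mol, lengths in Angstrom.
#' @slot family character, one of the supported family names.
#' @slot params named list of family-specific coefficients.
#' @slot dimension integer, 1 or 2.
#' @export
setClass("PotentialSpec",
  representation(family = "character", params = "list", dimension = "integer"),
  validity = function(object) {
    if (!object@family %in% c("harmonic", "double_well", "mueller_brown", "polynomial"))
      return(sprintf("unknown potential family '%s'", object@family))
    if (!object@dimension %in% c(1L, 2L)) return("dimension must be 1 or 2")
    TRUE
  })

#' @title Flat-bottom restraint
#' @description A restraint that is exactly zero inside \code{[lower, upper]}
#'   and rises as a half-harmonic wall \code{0.5 * stiffness * excess^2}
#'   outside, confining an observable without biasing the interior.
#' @slot observable name of the restrained coordinate ("rc1"/"rc2") or a
#'   label for a derived distance/angle.
#' @slot lower,upper flat-region bounds (Angstrom or degrees).
#' @slot stiffness wall stiffness (kcal/mol per unit squared).
#' @export
setClass("FlatBottomRestraint",
  representation(observable = "character", lower = "numeric", upper = "numeric",
                 stiffness = "numeric"),
  validity = function(object) {
    if (object@lower >= object@upper) return("lower bound must be < upper bound")
    if (object@stiffness < 0) return("stiffness must be >= 0")
    TRUE
  })

#' @title Thermostat and integrator parameters
#' @slot temperature bath temperature (K).
#' @slot friction friction coefficient of the overdamped integrator
#'   (kcal mol-1 ps A-2; sets the time scale, not the stationary law).
#' @slot timeStep integration time step (ps).
#' @slot seed RNG seed; identical seeds give bit-identical trajectories.
#' @slot steps number of integration steps.
#' @export
setClass("ThermostatParams",
  representation(temperature = "numeric", friction = "numeric", timeStep = "numeric",
                 seed = "integer", steps = "integer"),
  validity = function(object) {
    if (object@temperature < 0) return("temperature must be >= 0")
    if (object@timeStep <= 0) return("time step must be > 0")
    if (object@friction <= 0) return("friction must be > 0")
    if (object@steps < 1L) return("steps must be >= 1")
    TRUE
  })

#' @title Simulated trajectory
#' @slot times frame times (ps), strictly increasing.
#' @slot coords frame coordinates (Angstrom), one row per frame.
#' @slot energies potential (plus restraint) energy per frame (kcal/mol).
#' @export
setClass("Trajectory",
  representation(times = "numeric", coords = "matrix", energies = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    if (nrow(object@coords) != n || length(object@energies) != n)
      return("times, coords and energies must have equal length")
    if (n > 1 && any(diff(object@times) <= 0)) return("times must be strictly increasing")
    TRUE
  })

#' @title Energy-tagged reaction-coordinate samples
#' @description Per-conformation reaction-coordinate value(s) (Angstrom) and
#'   potential energy (kcal/mol); the raw material of all free-energy
#'   surfaces.
#' @slot rc matrix of reaction-coordinate values, one row per sample, 1 or 2
#'   columns named \code{rc1}(/\code{rc2}).
#' @slot energy energy per sample (kcal/mol), finite, no missing values.
#' @export
setClass("EnergySampleTable",
  representation(rc = "matrix", energy = "numeric"),
  validity = function(object) {
    if (nrow(object@rc) != length(object@energy))
      return("rc and energy must have the same number of rows")
    if (!ncol(object@rc) %in% 1:2) return("rc must have 1 or 2 columns")
    if (anyNA(object@energy) || any(!is.finite(object@energy)))
      return("energies must be finite and non-missing")
    if (anyNA(object@rc) || any(!is.finite(object@rc)))
      return("reaction-coordinate values must be finite and non-missing")
    TRUE
  })

#' @title Uniform binning grid
#' @description Per-axis bounds and bin counts.  Bins are half-open
#'   \code{[lo, hi)} except the last, which is closed; values exactly on an
#'   interior edge belong to the higher bin.
#' @slot lower,upper per-axis bounds (Angstrom).
#' @slot bins per-axis bin counts (>= 2).
#' @export
setClass("GridSpec",
  representation(lower = "numeric", upper = "numeric", bins = "integer"),
  validity = function(object) {
    d <- length(object@bins)
    if (length(object@lower) != d || length(object@upper) != d)
      return("lower, upper and bins must have equal length")
    if (!d %in% 1:2) return("grid must be 1- or 2-dimensional")
    if (any(object@upper <= object@lower)) return("upper must exceed lower on every axis")
    if (any(object@bins < 2L)) return("bin counts must be >= 2")
    TRUE
  })

#' @title Gridded 2D free-energy surface
#' @slot grid the \linkS4class{GridSpec} the surface lives on.
#' @slot raw raw per-bin free energy (kcal/mol), NA where unoccupied.
#' @slot smoothed LOESS-smoothed per-bin free energy; its occupied minimum
#'   is 0 by construction.
#' @slot occupancy per-bin sample counts.
#' @slot temperature estimation temperature (K).
#' @slot bootstrapSD per-bin bootstrap standard deviation (0x0 matrix until
#'   \code{bootstrapSurface} fills it).
#' @slot outOfRange number of dropped out-of-range samples.
#' @export
setClass("FreeEnergySurface",
  representation(grid = "GridSpec", raw = "matrix", smoothed = "matrix",
                 occupancy = "matrix", temperature = "numeric",
                 bootstrapSD = "matrix", outOfRange = "integer"),
  validity = function(object) {
    nb <- object@grid@bins
    if (length(nb) != 2L) return("surface grid must be 2-dimensional")
    for (nm in c("raw", "smoothed", "occupancy")) {
      m <- slot(object, nm)
      if (!all(dim(m) == nb)) return(sprintf("%s must be a %dx%d matrix", nm, nb[1], nb[2]))
    }
    occ <- is.finite(object@smoothed)
    if (any(occ) && abs(min(object@smoothed[occ])) > 1e-8)
      return("minimum of the smoothed occupied surface must be 0")
    TRUE
  })

#' @title 1D free-energy profile
#' @description Free energy along a single coordinate.  Estimated profiles
#'   are zero-referenced at their occupied minimum; path profiles (from
#'   \code{pathProfile}) are zero-referenced at the starting basin instead.
#' @slot centers bin centers or arc-length positions (Angstrom), strictly
#'   increasing.
#' @slot dg free energy per position (kcal/mol).
#' @slot raw unsmoothed values (may be length 0 for path profiles).
#' @slot occupancy per-bin counts (may be length 0).
#' @slot temperature temperature (K; NA for path profiles).
#' @slot bootstrapSD bootstrap SD (length 0 until computed).
#' @export
setClass("FreeEnergyProfile",
  representation(centers = "numeric", dg = "numeric", raw = "numeric",
                 occupancy = "numeric", temperature = "numeric",
                 bootstrapSD = "numeric"),
  validity = function(object) {
    n <- length(object@centers)
    if (length(object@dg) != n) return("centers and dg must have equal length")
    if (n > 1 && any(diff(object@centers) <= 0))
      return("centers must be strictly increasing")
    for (nm in c("raw", "occupancy", "bootstrapSD")) {
      v <- slot(object, nm)
      if (length(v) != 0L && length(v) != n)
        return(sprintf("%s must be empty or of length %d", nm, n))
    }
    TRUE
  })

#' @title Minimum-energy path on a gridded surface
#' @slot nodes k x 2 matrix of 1-based grid indices from S to P; consecutive
#'   rows are grid-adjacent under \code{connectivity}.
#' @slot dg free energy at each node (kcal/mol).
#' @slot arc cumulative arc length (Angstrom, Euclidean bin-center distance).
#' @slot barrier \eqn{\Delta G^\ddag} = max over the path minus the value at
#'   S (kcal/mol, >= 0).
#' @slot tsMain index (into the path) of the main transition state.
#' @slot tsIntermediate indices of intermediate transition states.
#' @slot connectivity 4 or 8.
#' @export
setClass("PathResult",
  representation(nodes = "matrix", dg = "numeric", arc = "numeric",
                 barrier = "numeric", tsMain = "integer",
                 tsIntermediate = "integer", connectivity = "integer"),
  validity = function(object) {
    k <- nrow(object@nodes)
    if (length(object@dg) != k || length(object@arc) != k)
      return("nodes, dg and arc must agree in length")
    if (object@barrier < -1e-12) return("barrier must be >= 0")
    if (k > 1) {
      steps <- abs(diff(object@nodes))
      maxstep <- apply(steps, 1, max)
      sumstep <- rowSums(steps)
      ok <- if (object@connectivity == 4L) (sumstep == 1) else (maxstep == 1)
      if (!all(ok)) return("consecutive path nodes must be grid-adjacent")
    }
    TRUE
  })

#' @title Set of local minima of a gridded surface
#' @slot nodes m x 2 matrix of 1-based grid indices (plateau minima are
#'   reported once, at their lexicographically lowest node).
#' @slot dg free energy at each minimum (kcal/mol).
#' @export
setClass("MinimaSet",
  representation(nodes = "matrix", dg = "numeric"),
  validity = function(object) {
    if (nrow(object@nodes) != length(object@dg))
      return("nodes and dg must agree in length")
    TRUE
  })

#' @title Steered-pulling trajectory record
#' @description Per-frame record of a constant-velocity harmonic-restraint
#'   pulling run: time (ns), pulled coordinate (Angstrom) and restraint
#'   center (Angstrom), plus the pulling protocol.  The restraint center is
#'   piecewise linear: constant for \code{holdDuration}, linear at
#'   \code{velocity} for \code{rampDuration}, constant again.
#' @slot times frame times (ns), strictly increasing.
#' @slot coord pulled coordinate per frame (Angstrom).
#' @slot center restraint center per frame (Angstrom).
#' @slot spring spring constant (kcal mol-1 A-2).
#' @slot velocity pulling velocity (A ns-1).
#' @slot holdDuration hold at start and end (ns).
#' @slot rampDuration constant-velocity segment duration (ns).
#' @export
setClass("SMDTrace",
  representation(times = "numeric", coord = "numeric", center = "numeric",
                 spring = "numeric", velocity = "numeric",
                 holdDuration = "numeric", rampDuration = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    if (length(object@coord) != n || length(object@center) != n)
      return("times, coord and center must have equal length")
    if (n > 1 && any(diff(object@times) <= 0)) return("times must be strictly increasing")
    expected <- .centerSchedule(object@times, object@center[1], object@velocity,
                                object@holdDuration, object@rampDuration)
    if (max(abs(object@center - expected)) > 1e-9)
      return("restraint center is inconsistent with the declared velocity/hold schedule")
    TRUE
  })

# piecewise-linear center schedule shared by the class validity, the
# simulator wrapper and the TSV reader
.centerSchedule <- function(times, center0, velocity, hold, ramp) {
  t1 <- pmin(pmax(times - hold, 0), ramp)
  center0 + velocity * t1
}

#' @title Accumulated pulling work
#' @slot displacement restraint-center displacement from the start
#'   (Angstrom, first element 0).
#' @slot work accumulated external work (kcal/mol, first element 0).
#' @export
setClass("WorkSeries",
  representation(displacement = "numeric", work = "numeric"),
  validity = function(object) {
    if (length(object@displacement) != length(object@work))
      return("displacement and work must have equal length")
    if (length(object@work) && abs(object@work[1]) > 1e-12)
      return("work must start at 0")
    TRUE
  })

#' @title Jarzynski free-energy difference estimate
#' @slot displacement common displacement grid (Angstrom, starts at 0).
#' @slot dg free-energy difference estimate per displacement (kcal/mol;
#'   dg[1] = 0 and dg <= mean work everywhere, by Jensen's inequality).
#' @slot ciLow,ciHigh bootstrap percentile 95% CI (NA until computed).
#' @slot nTraj number of trajectories in the ensemble.
#' @slot temperature temperature (K).
#' @export
setClass("JarzynskiResult",
  representation(displacement = "numeric", dg = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", nTraj = "integer", temperature = "numeric"),
  validity = function(object) {
    n <- length(object@displacement)
    if (length(object@dg) != n || length(object@ciLow) != n || length(object@ciHigh) != n)
      return("displacement, dg and CI vectors must have equal length")
    if (n && abs(object@dg[1]) > 1e-9) return("dg at zero displacement must be 0")
    TRUE
  })

#' @title Labelled distance time series
#' @slot times frame times (ns), strictly increasing.
#' @slot distances distances (Angstrom, >= 0).
#' @slot label observable label (e.g. "K1120-NZ - wat-O").
#' @export
setClass("DistanceSeries",
  representation(times = "numeric", distances = "numeric", label = "character"),
  validity = function(object) {
    if (length(object@times) != length(object@distances))
      return("times and distances must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    if (any(object@distances < 0)) return("distances must be >= 0")
    TRUE
  })

#' @title Labelled 3D coordinate frames
#' @slot frames list of n x 3 coordinate matrices (Angstrom), one per frame,
#'   with identical point count and ordering.
#' @slot labels point labels, one per row of each frame.
#' @slot reference index of the reference frame for superposition.
#' @export
setClass("CoordinateFrameSet",
  representation(frames = "list", labels = "character", reference = "integer"),
  validity = function(object) {
    if (!length(object@frames)) return("at least one frame is required")
    np <- length(object@labels)
    for (f in object@frames) {
      if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != np)
        return("every frame must be an n x 3 matrix matching the label count")
    }
    if (object@reference < 1L || object@reference > length(object@frames))
      return("reference frame index out of range")
    TRUE
  })

#' @title Analysis configuration
#' @description A validated, serializable bag of pipeline settings.  The
#'   JSON round trip \code{writeAnalysisConfig} / \code{readAnalysisConfig}
#'   reproduces the object exactly.
#' @slot values named list of settings (all numerics stored as doubles so
#'   that the JSON round trip is an identity).
#' @export
setClass("AnalysisConfig",
  representation(values = "list"),
  validity = function(object) {
    nm <- names(object@values)
    if (is.null(nm) || any(nm == "")) return("all config entries must be named")
    TRUE
  })
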